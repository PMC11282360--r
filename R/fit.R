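# Fitting the multitree mixture by the nested optimization workflow:
# parsimony/Jukes-Cantor initialization, then outer iterations that
# (i) recompute posterior site-to-class assignments (E-step),
# (ii) per class, optimize branch lengths by exact coordinate ascent and any
#     unlinked substitution/frequency parameters by quasi-Newton search on
#     the expected class log-likelihood (EM M-step),
# (iii) per class, update any unlinked gamma shape the same way,
# (iv) update the tree weights as mean posterior probabilities,
# (v) refine parameter blocks linked across classes by BFGS on the actual
#     mixture log-likelihood, rejecting worsening steps.
# All M-substeps increase the EM surrogate (or the likelihood directly), so
# the outer-iteration log-likelihood trace is non-decreasing; iteration stops
# when its increment falls below epsilon.

#' Which parameter blocks are linked in each submodel
#'
#' The six implemented submodels form a hierarchy from fully unlinked (1) to
#' fully linked (6). "Linked" means a single parameter block shared by all
#' mixture classes; branch lengths and tree weights are always per-class.
#' The two combinations with a linked substitution matrix but unlinked
#' frequencies are not expressible.
#'
#' @param submodel integer 1-6.
#' @return list with logical components `sub`, `freq`, `rhas` (`TRUE` =
#'   linked).
#' @export
submodel_linkage <- function(submodel) {
  submodel <- as.integer(submodel)
  if (is.na(submodel) || submodel < 1L || submodel > 6L)
    stop("'submodel' must be an integer in 1..6")
  switch(submodel,
         list(sub = FALSE, freq = FALSE, rhas = FALSE),
         list(sub = FALSE, freq = FALSE, rhas = TRUE),
         list(sub = FALSE, freq = TRUE,  rhas = FALSE),
         list(sub = FALSE, freq = TRUE,  rhas = TRUE),
         list(sub = TRUE,  freq = TRUE,  rhas = FALSE),
         list(sub = TRUE,  freq = TRUE,  rhas = TRUE))
}

#' Number of free parameters of a multitree mixture model
#'
#' Weights (m-1), branch lengths m(2t-3), exchangeabilities 5 per unlinked
#' class or 5 shared, frequencies 3 likewise, gamma shape 1 likewise. With a
#' single class the count equals the standard single-tree model's.
#'
#' @param submodel integer 1-6 (ignored distinctions vanish at m = 1).
#' @param m number of mixture classes.
#' @param ntaxa number of taxa t.
#' @return integer parameter count.
#' @export
count_free_parameters <- function(submodel, m, ntaxa) {
  lk <- submodel_linkage(submodel)
  (m - 1L) + m * (2L * ntaxa - 3L) +
    5L * (if (lk$sub) 1L else m) +
    3L * (if (lk$freq) 1L else m) +
    1L * (if (lk$rhas) 1L else m)
}

#' Bayesian information criterion
#'
#' `BIC = k log(N) - 2 l` with N the number of alignment sites.
#'
#' @param loglik maximized log-likelihood l.
#' @param k number of free parameters.
#' @param nsites number of sites N.
#' @return scalar BIC (lower is better).
#' @export
bic <- function(loglik, k, nsites) {
  if (nsites < 1) stop("'nsites' must be >= 1")
  k * log(nsites) - 2 * loglik
}

# -- parameter transforms for unconstrained optimization ---------------------
.encode_gtr <- function(r) log(pmin(pmax(r[1:5], 1e-4), 1e4))
.decode_gtr <- function(x) gtr_params(c(exp(pmin(pmax(x, -9), 9)), 1))
.encode_freq <- function(p) log(p[1:3] / p[4])
.decode_freq <- function(x) {
  x <- pmin(pmax(x, -12), 12)
  base_freqs(c(exp(x), 1) / (sum(exp(x)) + 1))
}

#' Fit the multitree mixture model
#'
#' Estimates the weights, branch lengths and (linked or unlinked) GTR
#' exchangeabilities, base frequencies and discrete-gamma shape of a mixture
#' across a fixed set of bifurcating tree topologies, by maximum likelihood.
#' Each site's likelihood is the weighted sum of its likelihood under every
#' class; see [class_site_log_likelihoods] and [mixture_site_likelihood].
#'
#' @param aln a [mast_alignment] or [compress_patterns] pattern alignment.
#' @param trees a `phylo`, `multiPhylo` or list of trees on the alignment
#'   taxa (topologies only; starting branch lengths come from parsimony).
#' @param submodel integer 1-6 selecting which parameter blocks are linked
#'   across classes (see [submodel_linkage]); irrelevant when only one tree
#'   is given.
#' @param ncat number of discrete-gamma rate categories (1 = homogeneous).
#' @param epsilon convergence threshold on outer-iteration log-likelihood
#'   increments.
#' @param weight_floor strict positivity floor on class weights.
#' @param min_bl,max_bl branch-length bounds.
#' @param max_outer maximum outer iterations; non-convergence is flagged.
#' @param sweeps maximum branch-length sweeps per class per outer iteration.
#' @param allow_duplicates permit duplicate input topologies.
#' @param init optional previous `mast_fit` on the same topologies (for
#'   example under a more-linked submodel) whose branch lengths, weights and
#'   model parameters seed this fit; hierarchical initialization of richer
#'   submodels from simpler ones shortens the climb considerably on long
#'   alignments.
#' @param verbose print per-iteration progress.
#' @return an object of class `mast_fit`; see [summary.mast_fit].
#' @export
mast <- function(aln, trees, submodel = 1L, ncat = 4L, epsilon = 1e-4,
                 weight_floor = 1e-6, min_bl = 1e-6, max_bl = 10,
                 max_outer = 200L, sweeps = 3L, allow_duplicates = FALSE,
                 init = NULL, verbose = FALSE) {
  cl <- match.call()
  paln <- if (inherits(aln, "pattern_alignment")) aln
          else compress_patterns(aln)
  trees <- validate_trees(trees, paln$labels, allow_duplicates)
  lk <- submodel_linkage(submodel)
  m <- length(trees)
  nt <- length(paln$labels)
  N <- paln$nsites
  patw <- as.numeric(paln$weights)
  npat <- length(patw)
  if (!is.finite(epsilon) || epsilon <= 0) stop("'epsilon' must be positive")
  ncat <- as.integer(ncat)
  sw_tol <- max(epsilon, 1e-4)

  # ---- initialization: Jukes-Cantor, parsimony branch lengths and weights
  # (or a previous fit on the same topologies)
  tipp_full <- tip_partials(paln)
  caches <- vector("list", m)
  BL <- vector("list", m)
  G <- rep(list(gtr_params()), m)
  FR <- rep(list(base_freqs()), m)
  alpha <- rep(1, m)
  init_map <- rep(NA_integer_, m)
  if (!is.null(init)) {
    stopifnot(inherits(init, "mast_fit"))
    init_map <- match(vapply(trees, topology_id, ""),
                      vapply(init$trees, topology_id, ""))
  }
  for (j in seq_len(m)) {
    if (!is.na(init_map[j])) {
      tr0 <- standardize_tree(init$trees[[init_map[j]]])
      G[[j]] <- init$gtr[[init_map[j]]]
      FR[[j]] <- init$freqs[[init_map[j]]]
      alpha[j] <- init$alpha[init_map[j]]
    } else {
      tr0 <- parsimony_branch_lengths(paln, trees[[j]], min_bl = min_bl)
    }
    caches[[j]] <- class_cache(paln, tr0, ncat, tipp_full)
    BL[[j]] <- pmin(pmax(caches[[j]]$bl, min_bl), max_bl)
  }
  if (!is.null(init) && !anyNA(init_map) && length(init$weights) == m) {
    w <- pmax(init$weights[init_map], weight_floor)
    w <- w / sum(w)
  } else {
    w <- initialize_weights(paln, trees, weight_floor)
  }

  rcache <- new.env()
  rates_of <- function(a) {
    key <- format(a, digits = 12)
    r <- rcache[[key]]
    if (is.null(r)) {
      r <- discretize_gamma(a, ncat)$rates
      rcache[[key]] <- r
    }
    r
  }
  lean_rm <- function(gtr, fr) {
    es <- gtr_eigen_cpp(as.numeric(gtr), as.numeric(fr))
    es$pi <- as.numeric(fr)
    es
  }
  peel_j <- function(j, gtr = G[[j]], fr = FR[[j]], a = alpha[j], bl = BL[[j]]) {
    rm <- lean_rm(gtr, fr)
    peeler_loglik(caches[[j]]$engine, bl, rates_of(a),
                  rm$vectors, rm$inv_vectors, rm$values, rm$pi)
  }
  all_logL <- function() vapply(seq_len(m), function(j) peel_j(j), numeric(npat))

  BADVAL <- 1e10
  # weighted class objective (negated) for unlinked blocks
  obj_class <- function(j, wt, gtr, fr, a) {
    v <- tryCatch(-sum(wt * peel_j(j, gtr, fr, a)), error = function(e) BADVAL)
    if (!is.finite(v)) BADVAL else v
  }
  # actual mixture objective (negated) for linked blocks
  obj_mix <- function(Gl, FRl, al) {
    v <- tryCatch({
      L <- vapply(seq_len(m), function(j)
        peel_j(j, Gl[[j]], FRl[[j]], al[j]), numeric(npat))
      -total_log_likelihood(L, w, patw)
    }, error = function(e) BADVAL)
    if (!is.finite(v)) BADVAL else v
  }

  # update scheduling for the costly parameter-block optimizations: blocks
  # whose last refresh gained little are revisited at geometrically growing
  # intervals (a skipped refresh is a no-op, so monotonicity is unaffected)
  # the "worth refreshing every iteration" gain threshold scales with the
  # magnitude of the log-likelihood so behavior is consistent across
  # alignment lengths
  skip_thresh <- function(ll) max(200 * epsilon, 2e-2, 1e-6 * abs(ll))
  sched <- new.env()
  sched$nxt <- list(); sched$span <- list()
  due <- function(key, iter) {
    nx <- sched$nxt[[key]]
    is.null(nx) || iter >= nx
  }
  record <- function(key, iter, gain, ll) {
    span <- if (gain > skip_thresh(ll)) 1L
            else min(2L * max(1L, sched$span[[key]] %||% 1L), 16L)
    sched$span[[key]] <- span
    sched$nxt[[key]] <- iter + span
  }

  # warm-up: fit the substitution parameters once against the whole
  # alignment (class-1 tree, all sites) and start every class there; the
  # per-class EM then only needs local refinement instead of m separate
  # JC-to-GTR climbs.  Skipped when starting from a previous fit.
  if (is.null(init)) {
    fnw <- function(par) {
      if (any(!is.finite(par))) return(BADVAL)
      gtr <- .decode_gtr(par[1:5])
      fr <- .decode_freq(par[6:8])
      a <- if (ncat > 1L) exp(min(max(par[9L], log(0.02)), log(100))) else 1
      obj_class(1L, patw, gtr, fr, a)
    }
    par0 <- c(.encode_gtr(G[[1L]]), .encode_freq(FR[[1L]]),
              if (ncat > 1L) log(alpha[1L]))
    opw <- stats::optim(par0, fnw, method = "BFGS",
                        control = list(maxit = 40L))
    if (opw$value < fnw(par0) && all(is.finite(opw$par))) {
      G <- rep(list(.decode_gtr(opw$par[1:5])), m)
      FR <- rep(list(.decode_freq(opw$par[6:8])), m)
      if (ncat > 1L)
        alpha <- rep(exp(min(max(opw$par[9L], log(0.02)), log(100))), m)
    }
  }

  logL <- all_logL()
  ll <- total_log_likelihood(logL, w, patw)
  trace_ll <- ll
  converged <- FALSE
  confirming <- FALSE       # deep full refresh before declaring convergence
  th1 <- NULL; th2 <- NULL  # iterate history for the EM extrapolation
  iter <- 0L

  # solve the (concave) weight subproblem at fixed class likelihoods by
  # iterating the mean-posterior update on row-scaled likelihoods; each step
  # is two matrix-vector products
  solve_weights <- function(logL, w) {
    mx <- do.call(pmax, as.data.frame(logL))
    Lt <- exp(logL - mx)
    wpat <- patw
    ll_of <- function(wv) sum(wpat * log(as.numeric(Lt %*% wv)))
    ll_w <- ll_of(w)
    for (wit in 1:500) {
      denom <- as.numeric(Lt %*% w)
      w_new <- as.numeric(crossprod(Lt, wpat / denom)) * w / N
      w_new <- pmax(w_new, weight_floor)
      w_new <- w_new / sum(w_new)
      ll_new <- ll_of(w_new)
      if (ll_new >= ll_w) w <- w_new
      if (ll_new - ll_w < epsilon / 10) break
      ll_w <- ll_new
    }
    w
  }


  while (iter < max_outer) {
    iter <- iter + 1L
    full_iter <- length(sched$nxt) == 0L ||
      all(vapply(sched$nxt, function(nx) nx <= iter, TRUE))
    deep <- iter <= 2L || confirming

    # ---- EM pass: one exact branch-length sweep per class against the
    # posterior-weighted patterns (iterated a little harder in the first
    # iterations), then the weight subproblem solved to convergence
    ll_ph0 <- total_log_likelihood(logL, w, patw)
    ll_ph <- ll_ph0
    ncyc <- 0L
    cyc_max <- if (iter <= 2L) 3L else 1L
    cls_due_j <- vapply(seq_len(m), function(j)
      (!lk$sub || (!lk$rhas && ncat > 1L)) &&
        (deep || due(paste0("cls", j), iter)), TRUE)
    for (cyc in seq_len(cyc_max)) {
      post <- if (m == 1L) matrix(1, npat, 1L) else posterior_assignment(logL, w)
      for (j in seq_len(m)) {
        # once past the early iterations, classes whose model block runs
        # this iteration are swept inside that block instead
        if (iter > 10L && cls_due_j[j]) next
        rm <- lean_rm(G[[j]], FR[[j]])
        res <- peeler_optimize(caches[[j]]$engine, BL[[j]], rates_of(alpha[j]),
                               rm$vectors, rm$inv_vectors, rm$values, rm$pi,
                               patw * post[, j], min_bl, max_bl,
                               as.integer(sweeps), sw_tol)
        if (isTRUE(res$improved)) BL[[j]] <- as.numeric(res$bl)
      }
      logL <- all_logL()
      if (m > 1L) w <- solve_weights(logL, w)
      ll_cyc <- total_log_likelihood(logL, w, patw)

      # quadratic extrapolation through the last three branch-length
      # iterates on the log scale (the weights are re-solved from the
      # current interior point); accepted only when it improves the
      # likelihood
      theta <- log(unlist(BL))
      if (!is.null(th2)) {
        r <- th1 - th2
        v <- (theta - th1) - r
        nv <- sqrt(sum(v^2))
        if (nv > 1e-12) {
          a_sq <- max(min(-sqrt(sum(r^2)) / nv, -1), -32)
          th_try <- th2 - 2 * a_sq * r + a_sq^2 * v
          BL_try <- BL
          ofs <- 0L
          for (j in seq_len(m)) {
            nj <- length(BL[[j]])
            BL_try[[j]] <- pmin(pmax(exp(th_try[(ofs + 1L):(ofs + nj)]),
                                     min_bl), max_bl)
            ofs <- ofs + nj
          }
          logL_try <- vapply(seq_len(m), function(j)
            peel_j(j, bl = BL_try[[j]]), numeric(npat))
          w_try <- if (m > 1L) solve_weights(logL_try, w) else w
          ll_try <- total_log_likelihood(logL_try, w_try, patw)
          if (ll_try > ll_cyc) {
            BL <- BL_try; w <- w_try; logL <- logL_try; ll_cyc <- ll_try
            theta <- log(unlist(BL))
            th1 <- NULL
          }
        }
      }
      th2 <- th1; th1 <- theta

      gain_cyc <- ll_cyc - ll_ph
      ll_ph <- ll_cyc
      ncyc <- cyc
      if (gain_cyc < epsilon) break
    }
    g_ph1 <- ll_ph - ll_ph0
    g_cls_tot <- 0

    # ---- model-parameter phase
    post <- if (m == 1L) matrix(1, npat, 1L) else posterior_assignment(logL, w)
    cls_ran <- FALSE
    for (j in seq_len(m)) {
      wt <- patw * post[, j]
      free_sub <- !lk$sub
      free_freq <- !lk$freq
      free_rhas <- !lk$rhas && ncat > 1L
      cls_due <- cls_due_j[j]

      # unlinked model blocks for this class: one quasi-Newton search over
      # all unlinked parameters jointly (exchangeabilities, frequencies,
      # gamma shape -- whichever are unlinked in this submodel) plus a log
      # tree-length scale (the shape and the overall branch-length scale lie
      # on a strongly coupled ridge), alternated with branch re-sweeps until
      # the class objective stops improving
      if (cls_due) {
        cls_ran <- TRUE
        mod_gain <- 0      # gain from model parameters alone (branch-sweep
                           # gains excluded so the scheduler can idle this)
        f_cur <- -obj_class(j, wt, G[[j]], FR[[j]], alpha[j])
        for (inner in seq_len(if (deep) 4L else 1L)) {
          par0 <- c(if (free_sub) .encode_gtr(G[[j]]),
                    if (free_freq) .encode_freq(FR[[j]]),
                    if (free_rhas) log(alpha[j]),
                    0)
          fn <- function(par) {
            if (any(!is.finite(par))) return(BADVAL)
            i <- 0L
            if (free_sub) { gtr <- .decode_gtr(par[1:5]); i <- 5L } else gtr <- G[[j]]
            if (free_freq) { fr <- .decode_freq(par[(i + 1L):(i + 3L)]); i <- i + 3L } else fr <- FR[[j]]
            if (free_rhas) { a <- exp(min(max(par[i + 1L], log(0.02)), log(100))); i <- i + 1L } else a <- alpha[j]
            s <- exp(min(max(par[i + 1L], -2), 2))
            bl <- pmin(pmax(BL[[j]] * s, min_bl), max_bl)
            v <- tryCatch(-sum(wt * peel_j(j, gtr, fr, a, bl)),
                          error = function(e) BADVAL)
            if (!is.finite(v)) BADVAL else v
          }
          f0 <- fn(par0)
          op <- stats::optim(par0, fn, method = "BFGS",
                             control = list(maxit = if (deep) 25L else 6L))
          if (op$value < f0 && all(is.finite(op$par))) {
            i <- 0L
            if (free_sub) { G[[j]] <- .decode_gtr(op$par[1:5]); i <- 5L }
            if (free_freq) { FR[[j]] <- .decode_freq(op$par[(i + 1L):(i + 3L)]); i <- i + 3L }
            if (free_rhas) { alpha[j] <- exp(min(max(op$par[i + 1L], log(0.02)), log(100))); i <- i + 1L }
            s <- exp(min(max(op$par[i + 1L], -2), 2))
            BL[[j]] <- pmin(pmax(BL[[j]] * s, min_bl), max_bl)
            mod_gain <- mod_gain + (f0 - op$value)
          }
          rm <- lean_rm(G[[j]], FR[[j]])
          res <- peeler_optimize(caches[[j]]$engine, BL[[j]],
                                 rates_of(alpha[j]),
                                 rm$vectors, rm$inv_vectors, rm$values,
                                 rm$pi, wt, min_bl, max_bl,
                                 as.integer(sweeps), sw_tol)
          if (isTRUE(res$improved)) BL[[j]] <- as.numeric(res$bl)
          gain <- res$loglik - f_cur
          f_cur <- max(res$loglik, f_cur)
          if (!deep || gain < sw_tol) break
        }
        record(paste0("cls", j), iter, mod_gain, ll_ph)
        g_cls_tot <- g_cls_tot + mod_gain
      }
    }

    if (cls_ran) {
      logL <- all_logL()
      if (m > 1L) w <- solve_weights(logL, w)
    }
    linked_ran <- FALSE

    # linked parameter blocks: one quasi-Newton search over all linked
    # parameters jointly (plus a common log tree-length scale), on the
    # actual mixture likelihood; worsening steps are rejected so the trace
    # stays monotone
    lsub <- lk$sub; lfreq <- lk$freq; lrhas <- lk$rhas && ncat > 1L
    if ((lsub || lfreq || lrhas) && (deep || due("linked", iter))) {
      linked_ran <- TRUE
      par0 <- c(if (lsub) .encode_gtr(G[[1L]]),
                if (lfreq) .encode_freq(FR[[1L]]),
                if (lrhas) log(alpha[1L]),
                0)
      dec_linked <- function(par) {
        i <- 0L
        if (lsub) { Gl <- rep(list(.decode_gtr(par[1:5])), m); i <- 5L } else Gl <- G
        if (lfreq) { FRl <- rep(list(.decode_freq(par[(i + 1L):(i + 3L)])), m); i <- i + 3L } else FRl <- FR
        if (lrhas) { al <- rep(exp(min(max(par[i + 1L], log(0.02)), log(100))), m); i <- i + 1L } else al <- alpha
        s <- exp(min(max(par[i + 1L], -2), 2))
        list(G = Gl, FR = FRl, alpha = al,
             BL = lapply(BL, function(b) pmin(pmax(b * s, min_bl), max_bl)))
      }
      fn <- function(par) {
        if (any(!is.finite(par))) return(BADVAL)
        st <- dec_linked(par)
        v <- tryCatch({
          L <- vapply(seq_len(m), function(j)
            peel_j(j, st$G[[j]], st$FR[[j]], st$alpha[j], st$BL[[j]]),
            numeric(npat))
          -total_log_likelihood(L, w, patw)
        }, error = function(e) BADVAL)
        if (!is.finite(v)) BADVAL else v
      }
      f0 <- fn(par0)
      op <- stats::optim(par0, fn, method = "BFGS",
                         control = list(maxit = if (deep) 20L else 4L))
      if (op$value < f0 && all(is.finite(op$par))) {
        st <- dec_linked(op$par)
        G <- st$G; FR <- st$FR; alpha <- st$alpha; BL <- st$BL
      }
      record("linked", iter, max(f0 - op$value, 0), ll_ph)
    }

    if (linked_ran) logL <- all_logL()
    ll_new <- total_log_likelihood(logL, w, patw)

    trace_ll <- c(trace_ll, ll_new)
    inc <- ll_new - ll
    ll <- ll_new
    if (verbose)
      message(sprintf("iter %3d  ll %.6f  inc %.6f  ph1 %.6f/%d  cls %.6f%s%s",
                      iter, ll_new, inc, g_ph1, ncyc, g_cls_tot, "",
                      if (confirming) "  [confirm]" else ""))
    if (iter >= 2L && inc < epsilon) {
      # only accept convergence after an iteration in which every parameter
      # block was refreshed with a deep optimizer pass; otherwise schedule
      # such a confirmation iteration
      if (confirming && full_iter) {
        converged <- TRUE
        break
      }
      sched$nxt <- list()
      sched$span <- list()
      confirming <- TRUE
    } else if (confirming && full_iter) {
      confirming <- FALSE      # confirmation found real improvement; go on
    }
  }

  fitted_trees <- vector("list", m)
  for (j in seq_len(m)) {
    tr <- caches[[j]]$tree
    tr$edge.length <- BL[[j]]
    fitted_trees[[j]] <- tr
  }
  k <- count_free_parameters(submodel, m, nt)
  post <- if (m == 1L) matrix(1, npat, 1L) else posterior_assignment(logL, w)
  structure(list(
    logLik = ll, df = k, nsites = N, npatterns = npat,
    BIC = bic(ll, k, N),
    weights = as.numeric(w),
    trees = structure(fitted_trees, class = "multiPhylo"),
    gtr = G, freqs = FR, alpha = alpha, ncat = ncat,
    submodel = as.integer(submodel), linkage = lk,
    epsilon = epsilon, weight_floor = weight_floor,
    converged = converged, iterations = iter, trace = trace_ll,
    class_logL = logL, posteriors = post,
    pattern_weights = patw, site_map = paln$site_map,
    taxa = paln$labels, call = cl), class = "mast_fit")
}

#' Fit the single-tree baseline model
#'
#' Maximum-likelihood branch lengths and GTR+G parameters on one fixed
#' topology; the BIC of this fit is the reference value against which the
#' mixture's BIC is compared. Identical to [mast] with a single input tree.
#'
#' @inheritParams mast
#' @param tree a single `phylo` topology.
#' @return a `mast_fit` with one class.
#' @export
mast_single_tree <- function(aln, tree, ncat = 4L, epsilon = 1e-4, ...) {
  if (inherits(tree, "multiPhylo")) {
    stopifnot(length(tree) == 1L)
    tree <- tree[[1L]]
  }
  mast(aln, list(tree), submodel = 6L, ncat = ncat, epsilon = epsilon, ...)
}
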