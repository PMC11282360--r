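# Experiment harnesses: parameter-recovery and model-selection studies on
# simulated mixtures, at desk scale by default.  The generating
# distributions below define the study conditions and are documented in the
# methods vignette.

#' Draw random substitution-model parameters for simulation
#'
#' Harness defaults: transversion exchangeabilities ~ U(0.5, 1.5),
#' transitions (AG, CT) ~ U(2, 5), rescaled so GT = 1; frequencies ~
#' Dirichlet(20,20,20,20); gamma shape ~ U(0.5, 2).
#'
#' @return list with `gtr`, `freqs`, `alpha`.
#' @export
draw_model_params <- function() {
  r <- c(stats::runif(1, 0.5, 1.5), stats::runif(1, 2, 5),
         stats::runif(3, 0.5, 1.5), 1)
  r[5] <- stats::runif(1, 2, 5)                 # CT transition
  f <- stats::rgamma(4, 20); f <- f / sum(f)
  list(gtr = gtr_params(r), freqs = base_freqs(f),
       alpha = stats::runif(1, 0.5, 2))
}

#' Draw random branch lengths for a topology
#'
#' Harness default: 0.01 + Exp(mean 0.08), capped at 0.7 substitutions/site.
#'
#' @param tree a `phylo` topology.
#' @return the tree with random branch lengths.
#' @export
draw_branch_lengths <- function(tree) {
  tree <- standardize_tree(tree)
  tree$edge.length <- pmin(0.01 + stats::rexp(nrow(tree$edge), 1 / 0.08), 0.7)
  tree
}

#' Draw random mixture weights
#'
#' Symmetric Dirichlet(6) proportions, redrawn until the smallest weight is
#' at least 0.5/m so that every class is represented.
#'
#' @param m number of classes.
#' @return weight vector summing to 1.
#' @export
draw_weights <- function(m) {
  if (m == 1L) return(1)
  for (i in 1:200) {
    w <- stats::rgamma(m, 6); w <- w / sum(w)
    if (min(w) >= 0.5 / m) return(w)
  }
  rep(1 / m, m)
}

#' Random tree set: one random topology plus SPR neighbors
#'
#' The first tree is a uniform random unrooted topology; each further tree
#' is 1-3 random SPR moves from the first, all pairwise distinct.
#'
#' @param ntaxa number of taxa.
#' @param m number of trees.
#' @param k_range SPR distances to draw from for the non-first trees.
#' @return a `multiPhylo` of topologies (no branch lengths).
#' @export
draw_tree_set <- function(ntaxa, m, k_range = 1:3) {
  t1 <- ape::rtopology(ntaxa, rooted = FALSE,
                       tip.label = paste0("t", seq_len(ntaxa)))
  if (m == 1L) return(structure(list(t1), class = "multiPhylo"))
  out <- list(t1)
  seen <- topology_id(t1)
  for (j in 2:m) {
    for (try in 1:200) {
      k <- sample(k_range, 1L)
      cand <- random_spr_neighbors(t1, k = k, count = 1L, distinct = FALSE)[[1L]]
      id <- topology_id(cand)
      if (!(id %in% seen)) { out[[j]] <- cand; seen <- c(seen, id); break }
    }
    if (length(out) < j) stop("could not draw ", m, " distinct topologies")
  }
  structure(out, class = "multiPhylo")
}

# simulate one mixture dataset under a submodel; returns alignment, labels,
# true weights/trees/params
sim_mixture_dataset <- function(m, ntaxa, nsites, submodel = 1L,
                                mode = "block") {
  lk <- submodel_linkage(submodel)
  trees <- draw_tree_set(ntaxa, m)
  w <- draw_weights(m)
  shared <- draw_model_params()
  classes <- vector("list", m)
  for (j in seq_len(m)) {
    p <- if (lk$sub && lk$freq && lk$rhas) shared else {
      pj <- draw_model_params()
      list(gtr = if (lk$sub) shared$gtr else pj$gtr,
           freqs = if (lk$freq) shared$freqs else pj$freqs,
           alpha = if (lk$rhas) shared$alpha else pj$alpha)
    }
    classes[[j]] <- class_model(draw_branch_lengths(trees[[j]]),
                                p$gtr, p$freqs, discretize_gamma(p$alpha, 4L))
  }
  spec <- mixture_sim_spec(classes, weights = w, length = nsites, mode = mode)
  sim <- simulate_mixture(spec)
  list(alignment = sim$alignment, labels = sim$labels, weights = w,
       trees = trees, classes = classes)
}

#' Weight-recovery experiment under the correctly specified model
#'
#' Simulates replicate mixtures of m trees on t taxa (block assignment of
#' sites to classes), fits the matching submodel with the true topologies,
#' and records the per-replicate RMSE between estimated and true weights
#' (and optionally the BIC difference to a single-tree fit on the
#' highest-weight true tree).
#'
#' @param m,ntaxa,nsites simulation dimensions.
#' @param submodel MAST submodel used both to simulate and to fit.
#' @param reps number of replicates.
#' @param seed RNG seed (one stream for the whole experiment).
#' @param compute_bic0 also fit the single-tree baseline.
#' @param epsilon convergence threshold passed to [mast].
#' @param max_outer outer-iteration cap passed to [mast] (the tree weights
#'   stabilize long before the final branch-length refinements).
#' @param staged initialize the unlinked fit from a fully linked fit
#'   (hierarchical initialization; useful on long alignments).
#' @return data frame with one row per replicate: `rmse_w`, `bic`, and, if
#'   requested, `bic0` and `dbic = bic - bic0`.
#' @export
experiment_recovery <- function(m, ntaxa, nsites, submodel = 1L, reps = 10L,
                                seed = 1L, compute_bic0 = FALSE,
                                epsilon = 1e-4, max_outer = 25L,
                                staged = FALSE) {
  set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    d <- sim_mixture_dataset(m, ntaxa, nsites, submodel)
    init <- if (staged && submodel != 6L)
      mast(d$alignment, d$trees, submodel = 6L, epsilon = epsilon,
           max_outer = max_outer) else NULL
    fit <- mast(d$alignment, d$trees, submodel = submodel, epsilon = epsilon,
                max_outer = max_outer, init = init)
    row <- data.frame(rep = r, rmse_w = weight_rmse(fit$weights, d$weights),
                      loglik = fit$logLik, bic = fit$BIC,
                      converged = fit$converged)
    if (compute_bic0) {
      f0 <- mast_single_tree(d$alignment, d$trees[[which.max(d$weights)]],
                             epsilon = epsilon, max_outer = max_outer)
      row$bic0 <- f0$BIC
      row$dbic <- row$bic - row$bic0
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}

#' Misspecification experiment: extra trees with no support in the data
#'
#' Simulates single-tree data, then fits a mixture whose classes are the
#' true tree plus `m - 1` trees each `k` random SPR moves away. Records
#' whether the true tree receives the maximum weight, and the BIC difference
#' to the single-tree fit on the true tree.
#'
#' @param ntaxa,nsites simulation dimensions.
#' @param m number of trees in the fitted mixture (>= 2).
#' @param k SPR distance of each incorrect tree from the truth.
#' @param submodel fitted MAST submodel.
#' @param reps,seed replication control.
#' @param epsilon convergence threshold passed to [mast].
#' @return data frame: `true_has_max` (logical), `w_true`, `bic`, `bic0`,
#'   `dbic` per replicate.
#' @export
experiment_misspecified <- function(ntaxa, nsites, m = 2L, k = 2L,
                                    submodel = 1L, reps = 10L, seed = 1L,
                                    epsilon = 1e-4, max_outer = 25L) {
  set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    true_tree <- draw_branch_lengths(
      ape::rtopology(ntaxa, rooted = FALSE,
                     tip.label = paste0("t", seq_len(ntaxa))))
    p <- draw_model_params()
    cm <- class_model(true_tree, p$gtr, p$freqs, discretize_gamma(p$alpha, 4L))
    aln <- simulate_alignment(true_tree, cm, nsites)
    extras <- random_spr_neighbors(true_tree, k = k, count = m - 1L)
    trees <- structure(c(list(true_tree), unclass(extras)),
                       class = "multiPhylo")
    fit <- mast(aln, trees, submodel = submodel, epsilon = epsilon,
                max_outer = max_outer)
    f0 <- mast_single_tree(aln, true_tree, epsilon = epsilon,
                           max_outer = max_outer)
    out[[r]] <- data.frame(rep = r,
                           true_has_max = which.max(fit$weights) == 1L,
                           w_true = fit$weights[1L],
                           bic = fit$BIC, bic0 = f0$BIC,
                           dbic = fit$BIC - f0$BIC)
  }
  do.call(rbind, out)
}

#' All-topologies model-selection experiment (5 taxa)
#'
#' Simulates data under two equally weighted random 5-tip trees (linked
#' submodel 6), fits the mixture of all 15 possible 5-taxon topologies,
#' ranks the candidate trees by fitted weight, then scores by BIC the
#' single-tree model (on the top-ranked tree), the mixture of the two true
#' trees, and mixtures formed by sequentially adding the remaining trees in
#' descending weight order (up to `max_extra` additions). Records whether
#' the two-true-tree mixture attains the minimum BIC.
#'
#' @param nsites alignment length.
#' @param reps,seed replication control.
#' @param max_extra how many sequentially added trees to score.
#' @param epsilon convergence threshold passed to [mast].
#' @return data frame per replicate: `true2_best` (logical), ranks of the
#'   true trees among the 15 weights, and the scored BIC values.
#' @export
experiment_all_topologies <- function(nsites = 1e5, reps = 10L, seed = 1L,
                                      max_extra = 3L, epsilon = 1e-4,
                                      max_outer = 25L) {
  set.seed(seed)
  tips <- paste0("t", 1:5)
  all15 <- all_topologies_5taxa(tips)
  ids15 <- vapply(all15, topology_id, "")
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    two <- all15[sample.int(15L, 2L)]
    classes <- lapply(two, function(tr) {
      p <- draw_model_params()
      class_model(draw_branch_lengths(tr), p$gtr, p$freqs,
                  discretize_gamma(p$alpha, 4L))
    })
    # linked simulation: same model in both classes
    p <- draw_model_params()
    for (j in 1:2)
      classes[[j]] <- class_model(classes[[j]]$tree, p$gtr, p$freqs,
                                  discretize_gamma(p$alpha, 4L))
    sim <- simulate_mixture(mixture_sim_spec(classes, weights = c(0.5, 0.5),
                                             length = nsites, mode = "block"))
    fit15 <- mast(sim$alignment, all15, submodel = 6L, epsilon = epsilon,
                  max_outer = max_outer)
    true_idx <- match(vapply(two, topology_id, ""), ids15)
    rk <- rank(-fit15$weights, ties.method = "first")
    ord <- order(fit15$weights, decreasing = TRUE)
    f1 <- mast_single_tree(sim$alignment, all15[[ord[1L]]], epsilon = epsilon,
                           max_outer = max_outer)
    f2 <- mast(sim$alignment, all15[true_idx], submodel = 6L, epsilon = epsilon,
               max_outer = max_outer)
    bics <- c(single = f1$BIC, true2 = f2$BIC)
    added <- setdiff(ord, true_idx)
    cur <- true_idx
    for (e in seq_len(min(max_extra, length(added)))) {
      cur <- c(cur, added[e])
      fe <- mast(sim$alignment, all15[cur], submodel = 6L, epsilon = epsilon,
                 max_outer = max_outer)
      bics <- c(bics, stats::setNames(fe$BIC, paste0("plus", e)))
    }
    out[[r]] <- data.frame(rep = r, true2_best = bics["true2"] == min(bics),
                           rank1 = rk[true_idx[1L]], rank2 = rk[true_idx[2L]],
                           t(bics))
  }
  do.call(rbind, out)
}

#' All 15 unrooted topologies on 5 taxa
#'
#' Built by inserting the fifth tip on every edge of every 4-taxon topology.
#'
#' @param tips 5 taxon labels.
#' @return a `multiPhylo` of 15 distinct topologies.
#' @export
all_topologies_5taxa <- function(tips = paste0("t", 1:5)) {
  stopifnot(length(tips) == 5L)
  q <- list(sprintf("((%s,%s),(%s,%s));", tips[1], tips[2], tips[3], tips[4]),
            sprintf("((%s,%s),(%s,%s));", tips[1], tips[3], tips[2], tips[4]),
            sprintf("((%s,%s),(%s,%s));", tips[1], tips[4], tips[2], tips[3]))
  out <- list()
  seen <- character(0)
  for (txt in q) {
    t4 <- standardize_tree(ape::read.tree(text = txt))
    g <- adj_from_tree(t4)
    for (a in seq_along(g$adj)) {
      for (b in g$adj[[a]]) {
        if (b < a) next
        g2 <- g
        w <- length(g2$adj) + 1L
        v <- w + 1L
        g2$adj[[a]] <- c(setdiff(g2$adj[[a]], b), w)
        g2$adj[[b]] <- c(setdiff(g2$adj[[b]], a), w)
        g2$adj[[w]] <- c(a, b, v)
        g2$adj[[v]] <- w
        g2$labels <- c(g2$labels, NA, tips[5])
        tr <- newick_from_adj(g2)
        id <- topology_id(tr)
        if (!(id %in% seen)) { out[[length(out) + 1L]] <- tr; seen <- c(seen, id) }
      }
    }
  }
  stopifnot(length(out) == 15L)
  structure(out, class = "multiPhylo")
}

#' Introgression experiment
#'
#' For each introgression rate, samples gene trees from the 4-taxon
#' coalescent with an introgression pulse, simulates and concatenates
#' per-gene alignments, fits the linked mixture (submodel 6) over the three
#' possible quartet topologies, and compares the fitted weights with the
#' simulated per-site topology proportions.
#'
#' @param rates introgression rates to run.
#' @param genes,gene_length simulation size per rate.
#' @param seed RNG seed.
#' @param epsilon convergence threshold passed to [mast].
#' @return data frame per rate: simulated proportions (`sim_TE1..3`), fitted
#'   weights (`w_TE1..3`), and the single-tree/mixture BIC difference.
#' @export
experiment_introgression <- function(rates = c(0, 0.5, 1), genes = 100L,
                                     gene_length = 200L, seed = 1L,
                                     epsilon = 1e-4, max_outer = 25L) {
  set.seed(seed)
  p <- draw_model_params()
  topo3 <- structure(list(
    ape::read.tree(text = "((t1,t2),(t3,t4));"),
    ape::read.tree(text = "((t2,t4),(t1,t3));"),
    ape::read.tree(text = "((t1,t4),(t2,t3));")), class = "multiPhylo")
  out <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    spec <- introgression_spec(rates[i], genes = genes,
                               gene_length = gene_length)
    gt <- sample_introgression_gene_trees(spec)
    cm <- class_model(topo3[[1L]], p$gtr, p$freqs, discretize_gamma(p$alpha, 4L))
    sim <- rescale_and_simulate_genes(gt, cm, factor = spec$scale,
                                      gene_length = gene_length)
    prop <- prop.table(table(factor(attr(sim, "topology"),
                                    levels = c("TE1", "TE2", "TE3"))))
    fit <- mast(sim$alignment, topo3, submodel = 6L, epsilon = epsilon,
                max_outer = max_outer)
    f0 <- mast_single_tree(sim$alignment, topo3[[which.max(fit$weights)]],
                           epsilon = epsilon, max_outer = max_outer)
    out[[i]] <- data.frame(rate = rates[i],
                           sim_TE1 = prop[1], sim_TE2 = prop[2], sim_TE3 = prop[3],
                           w_TE1 = fit$weights[1], w_TE2 = fit$weights[2],
                           w_TE3 = fit$weights[3],
                           dbic = fit$BIC - f0$BIC)
  }
  do.call(rbind, out)
}

#' Run a named experiment
#'
#' Dispatcher over the experiment harnesses with desk-scale defaults:
#' `"recovery_unlinked"`/`"recovery_linked"` (weight recovery under
#' submodels 1/6), `"misspecified"` (single-tree data, extra SPR trees),
#' `"all_topologies"` (5-taxon BIC selection) and `"introgression"`.
#'
#' @param name experiment name.
#' @param ... overrides passed to the harness.
#' @param seed RNG seed.
#' @return the harness's per-replicate data frame.
#' @export
run_experiment <- function(name = c("recovery_unlinked", "recovery_linked",
                                    "misspecified", "all_topologies",
                                    "introgression"),
                           ..., seed = 1L) {
  name <- match.arg(name)
  switch(name,
    recovery_unlinked = experiment_recovery(m = 2L, ntaxa = 10L,
                                            nsites = 5000L, submodel = 1L,
                                            seed = seed, ...),
    recovery_linked = experiment_recovery(m = 2L, ntaxa = 10L,
                                          nsites = 5000L, submodel = 6L,
                                          seed = seed, ...),
    misspecified = experiment_misspecified(ntaxa = 7L, nsites = 10000L,
                                           seed = seed, ...),
    all_topologies = experiment_all_topologies(seed = seed, ...),
    introgression = experiment_introgression(seed = seed, ...))
}
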