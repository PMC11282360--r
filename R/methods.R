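# S3 methods for fitted multitree mixtures.

#' @export
print.mast_fit <- function(x, digits = 4, ...) {
  m <- length(x$weights)
  cat("Multitree mixture fit (", if (m == 1L) "single tree" else
      paste0(m, " classes, submodel ", x$submodel), ")\n", sep = "")
  cat("  log-likelihood:", format(x$logLik, digits = 10),
      " df:", x$df, " BIC:", format(x$BIC, digits = 10), "\n")
  cat("  sites:", x$nsites, " patterns:", x$npatterns,
      " outer iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (m > 1L)
    cat("  weights:", paste(format(x$weights, digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' Summarize a multitree mixture fit
#'
#' @param object a `mast_fit`.
#' @param ... unused.
#' @return a `summary.mast_fit` with per-class weights, tree lengths and
#'   model parameters.
#' @export
summary.mast_fit <- function(object, ...) {
  m <- length(object$weights)
  cls <- data.frame(
    class = seq_len(m),
    weight = object$weights,
    tree_length = vapply(object$trees, function(t) sum(t$edge.length), 0),
    alpha = object$alpha)
  structure(list(fit = object, classes = cls), class = "summary.mast_fit")
}

#' @export
print.summary.mast_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nPer-class summary:\n")
  print(x$classes, digits = digits, row.names = FALSE)
  lk <- x$fit$linkage
  cat("\nExchangeabilities (AC AG AT CG CT GT)",
      if (lk$sub) "[linked]" else "[unlinked]", "\n")
  gs <- if (lk$sub) x$fit$gtr[1L] else x$fit$gtr
  for (g in gs) cat(" ", paste(format(unclass(g), digits = digits), collapse = " "), "\n")
  cat("Base frequencies (A C G T)",
      if (lk$freq) "[linked]" else "[unlinked]", "\n")
  fs <- if (lk$freq) x$fit$freqs[1L] else x$fit$freqs
  for (f in fs) cat(" ", paste(format(unclass(f), digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.mast_fit <- function(object, ...) {
  m <- length(object$weights)
  out <- c(stats::setNames(object$weights, paste0("w", seq_len(m))))
  lk <- object$linkage
  gidx <- if (lk$sub) 1L else seq_len(m)
  for (j in gidx)
    out <- c(out, stats::setNames(unclass(object$gtr[[j]])[1:5],
             paste0(if (lk$sub) "" else paste0("c", j, "."),
                    c("rAC", "rAG", "rAT", "rCG", "rCT"))))
  fidx <- if (lk$freq) 1L else seq_len(m)
  for (j in fidx)
    out <- c(out, stats::setNames(unclass(object$freqs[[j]]),
             paste0(if (lk$freq) "" else paste0("c", j, "."),
                    c("piA", "piC", "piG", "piT"))))
  aidx <- if (lk$rhas) 1L else seq_len(m)
  out <- c(out, stats::setNames(object$alpha[aidx],
           if (lk$rhas) "alpha" else paste0("c", aidx, ".alpha")))
  out
}

#' @export
logLik.mast_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$nsites,
            class = "logLik")
}

#' Per-site posterior class probabilities
#'
#' Expands the per-pattern posterior assignments back to alignment sites
#' (1-based site indices).
#'
#' @param object a `mast_fit`.
#' @param ... unused.
#' @return data frame with columns `site`, `logL` (log mixture likelihood of
#'   the site) and `p1..pm` (posterior probability of each class).
#' @export
predict.mast_fit <- function(object, ...) {
  lmix <- mixture_site_likelihood(object$class_logL, object$weights)
  idx <- object$site_map
  out <- data.frame(site = seq_along(idx), logL = lmix[idx])
  p <- object$posteriors[idx, , drop = FALSE]
  colnames(p) <- paste0("p", seq_len(ncol(p)))
  cbind(out, as.data.frame(p))
}

#' Write per-site posterior probabilities to TSV
#'
#' @param fit a `mast_fit`.
#' @param path output file.
#' @export
write_site_posteriors <- function(fit, path) {
  utils::write.table(predict(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot the optimization trace or site posteriors of a fit
#'
#' @param x a `mast_fit`.
#' @param which `"trace"` (log-likelihood per outer iteration) or
#'   `"posteriors"` (per-site posterior of each class along the alignment).
#' @param ... passed to the underlying plotting calls.
#' @export
plot.mast_fit <- function(x, which = c("trace", "posteriors"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "b",
                   xlab = "outer iteration", ylab = "log-likelihood", ...)
  } else {
    p <- x$posteriors[x$site_map, , drop = FALSE]
    graphics::matplot(seq_len(nrow(p)), p, type = "l", lty = 1,
                      xlab = "site", ylab = "posterior probability", ...)
  }
  invisible(x)
}

#' Simulate alignments from a fitted multitree mixture
#'
#' Draws each site's class from the fitted weights and evolves it along the
#' fitted tree under the fitted model (iid site assignment).
#'
#' @param object a `mast_fit`.
#' @param nsim number of alignments.
#' @param seed optional RNG seed.
#' @param nsites alignment length (defaults to the fitted data's length).
#' @param ... unused.
#' @return a list of [mast_alignment] objects (with per-site true class
#'   labels as attribute `labels`).
#' @export
simulate.mast_fit <- function(object, nsim = 1, seed = NULL, nsites = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nsites)) nsites <- object$nsites
  spec <- mixture_sim_spec(
    classes = lapply(seq_along(object$weights), function(j)
      class_model(object$trees[[j]], object$gtr[[j]], object$freqs[[j]],
                  discretize_gamma(object$alpha[j], object$ncat))),
    weights = object$weights, length = nsites, mode = "iid")
  replicate(nsim, simulate_mixture(spec), simplify = FALSE)
}
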