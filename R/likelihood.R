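# Likelihood engine: per-site, per-class log-likelihoods by Felsenstein
# pruning (C++ kernel), and the mixture quantities built from them.  All
# per-site computation is done over distinct site patterns and expanded only
# on output.

# Cache the per-class quantities that do not change within a fit: postorder
# edge matrix, tip partials ordered by the tree's tips, and the persistent
# C++ engine holding all pruning work buffers.
class_cache <- function(paln, tree, ncat, tipp_full = NULL) {
  tr <- ape::reorder.phylo(standardize_tree(tree), "postorder")
  if (is.null(tipp_full)) tipp_full <- tip_partials(paln)
  ord <- match(tr$tip.label, paln$labels)
  if (anyNA(ord)) stop("tree tips do not match alignment taxa: ",
                       paste(tr$tip.label[is.na(ord)], collapse = ", "))
  tipp <- tipp_full[, , ord, drop = FALSE]
  npat <- ncol(tipp)
  list(tree = tr, edge = tr$edge, ntip = length(tr$tip.label),
       bl = tr$edge.length, npat = npat,
       engine = peeler_create(tr$edge, length(tr$tip.label), tipp,
                              npat, as.integer(ncat)))
}

peel_class <- function(cache, gtr, freqs, alpha, ncat, bl = cache$bl) {
  rm <- build_rate_matrix(gtr, freqs)
  rates <- discretize_gamma(alpha, ncat)$rates
  peeler_loglik(cache$engine, bl, rates,
                rm$vectors, rm$inv_vectors, rm$values, rm$pi)
}

#' Per-pattern log-likelihoods of one mixture class
#'
#' Felsenstein pruning over the distinct site patterns of an alignment under
#' one class (topology, branch lengths, GTR, frequencies, discrete-gamma
#' rates), with per-node scaling so no pattern underflows. The returned value
#' for pattern i is \eqn{\log \sum_k (1/K) L_{ik}} over the K gamma
#' categories.
#'
#' @param paln a [compress_patterns] pattern alignment.
#' @param cm a [class_model].
#' @return numeric vector of per-pattern log-likelihoods.
#' @export
class_site_log_likelihoods <- function(paln, cm) {
  stopifnot(inherits(paln, "pattern_alignment"), inherits(cm, "class_model"))
  cache <- class_cache(paln, cm$tree, cm$rhas$ncat)
  peel_class(cache, cm$gtr, cm$freqs, cm$rhas$alpha, cm$rhas$ncat)
}

#' Per-pattern log mixture likelihood
#'
#' The log of the weighted sum of class likelihoods,
#' \eqn{\log L_i = \log \sum_j w_j L_{ij}}, evaluated by log-sum-exp.
#'
#' @param logL patterns x classes matrix of per-pattern class
#'   log-likelihoods.
#' @param w strictly positive weight vector summing to 1, one per class.
#' @return numeric vector of per-pattern log mixture likelihoods.
#' @export
mixture_site_likelihood <- function(logL, w) {
  logL <- as.matrix(logL)
  if (length(w) != ncol(logL))
    stop("weight vector length ", length(w), " != class count ", ncol(logL))
  if (any(w <= 0)) stop("class weights must be strictly positive")
  A <- sweep(logL, 2L, log(w), "+")
  m <- do.call(pmax, c(as.data.frame(A), na.rm = FALSE))
  m + log(rowSums(exp(A - m)))
}

#' Total log-likelihood over all sites
#'
#' Pattern-weighted sum of per-pattern log mixture likelihoods; identical to
#' the per-site sum over the uncompressed alignment.
#'
#' @inheritParams mixture_site_likelihood
#' @param weights pattern multiplicities (from the pattern alignment).
#' @return scalar log-likelihood.
#' @export
total_log_likelihood <- function(logL, w, weights) {
  lmix <- mixture_site_likelihood(logL, w)
  if (length(weights) != length(lmix)) stop("pattern weight length mismatch")
  sum(weights * lmix)
}

#' Posterior class membership of each site pattern
#'
#' \eqn{p_{ij} = w_j L_{ij} / \sum_k w_k L_{ik}}, computed in log space; each
#' row sums to 1.
#'
#' @inheritParams mixture_site_likelihood
#' @return patterns x classes matrix of posterior probabilities.
#' @export
posterior_assignment <- function(logL, w) {
  logL <- as.matrix(logL)
  A <- sweep(logL, 2L, log(w), "+")
  lmix <- mixture_site_likelihood(logL, w)
  p <- exp(A - lmix)
  p / rowSums(p)
}

#' Expected class log-likelihood
#'
#' The expectation of a class's log-likelihood over sites under the posterior
#' site assignments: \eqn{E[l_j] = \sum_i p_{ij} \log L_{ij}} (pattern-
#' weighted). This is the per-class objective of the EM M-step.
#'
#' @param p posterior probabilities for the class, one per pattern.
#' @param class_logL per-pattern class log-likelihoods.
#' @param weights pattern multiplicities.
#' @return scalar.
#' @export
expected_class_log_likelihood <- function(p, class_logL, weights) {
  sum(weights * p * class_logL)
}
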