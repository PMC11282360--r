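#' GTR exchangeability parameters
#'
#' Constructs the set of relative substitution rates of the general
#' time-reversible model in the order AC, AG, AT, CG, CT, GT. The last
#' exchangeability (GT) acts as the fixed reference: the vector is rescaled so
#' that GT = 1, leaving 5 free parameters. All rates equal gives the
#' Jukes-Cantor special case.
#'
#' @param rates numeric vector of 6 positive exchangeabilities
#'   (AC, AG, AT, CG, CT, GT).
#' @return an object of class `gtr_params` (numeric length 6, GT = 1).
#' @export
gtr_params <- function(rates = rep(1, 6)) {
  rates <- as.numeric(rates)
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates <= 0))
    stop("'rates' must be 6 positive finite exchangeabilities (AC, AG, AT, CG, CT, GT)")
  rates <- rates / rates[6L]
  names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  structure(rates, class = "gtr_params")
}

#' Stationary base frequencies
#'
#' @param pi numeric vector of 4 positive frequencies (A, C, G, T); rescaled
#'   to sum to 1.
#' @return an object of class `base_freqs`.
#' @export
base_freqs <- function(pi = rep(0.25, 4)) {
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0))
    stop("'pi' must be 4 positive finite frequencies (A, C, G, T)")
  pi <- pi / sum(pi)
  names(pi) <- c("A", "C", "G", "T")
  structure(pi, class = "base_freqs")
}

#' Discrete-gamma rate heterogeneity
#'
#' Discretizes a unit-mean gamma distribution of site rates into `ncat`
#' equal-probability categories. Each category rate is the mean of the gamma
#' density over the category's quantile interval (the same convention used by
#' most likelihood packages), which keeps the weighted mean rate exactly 1;
#' a final renormalization guards against round-off.
#'
#' @param alpha gamma shape parameter (> 0). Smaller values mean stronger
#'   rate heterogeneity across sites.
#' @param ncat number of discrete categories (default 4). `ncat = 1` yields a
#'   single category of rate 1 (rate homogeneity).
#' @return an object of class `gamma_rhas`: list with `alpha`, `ncat`,
#'   `rates` (length `ncat`, mean 1) and `probs` (uniform `1/ncat`).
#' @export
discretize_gamma <- function(alpha, ncat = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  ncat <- as.integer(ncat)
  if (is.na(ncat) || ncat < 1L) stop("'ncat' must be a positive integer")
  if (ncat == 1L) {
    rates <- 1
  } else {
    q <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha, rate = alpha)
    # mean of a Gamma(a, a) over (q_lo, q_hi] with probability 1/ncat:
    # ncat * [P(a+1, a*q_hi) - P(a+1, a*q_lo)]
    rates <- ncat * (stats::pgamma(q[-1L], alpha + 1, alpha) -
                     stats::pgamma(q[-(ncat + 1L)], alpha + 1, alpha))
    rates <- rates / mean(rates)
  }
  structure(list(alpha = alpha, ncat = ncat, rates = rates,
                 probs = rep(1 / ncat, ncat)),
            class = "gamma_rhas")
}

#' Build a normalized GTR instantaneous rate matrix
#'
#' Assembles Q with off-diagonals \eqn{Q_{ij} = r_{ij} \pi_j}, diagonals set
#' for zero row sums, rescaled so the expected number of substitutions per
#' unit branch length is 1 (\eqn{-\sum_i \pi_i Q_{ii} = 1}). The matrix is
#' time-reversible (\eqn{\pi_i Q_{ij} = \pi_j Q_{ji}}) by construction, which
#' permits a numerically stable eigendecomposition through the symmetrized
#' matrix \eqn{\Pi^{1/2} Q \Pi^{-1/2}}; the decomposition is computed once and
#' cached in the returned object.
#'
#' @param gtr a [gtr_params] object (or vector of 6 rates).
#' @param freqs a [base_freqs] object (or vector of 4 frequencies).
#' @return an object of class `rate_matrix`: list with `Q`, `pi`, and cached
#'   eigen system (`values`, `vectors`, `inv_vectors`).
#' @export
build_rate_matrix <- function(gtr = gtr_params(), freqs = base_freqs()) {
  if (!inherits(gtr, "gtr_params")) gtr <- gtr_params(gtr)
  if (!inherits(freqs, "base_freqs")) freqs <- base_freqs(freqs)
  r <- unclass(gtr); pi <- unclass(freqs)
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (!is.finite(mu) || mu <= 0) stop("degenerate rate matrix: mean rate is not positive")
  Q <- Q / mu
  sp <- sqrt(pi)
  S <- Q * outer(sp, 1 / sp)         # symmetric similarity transform
  S <- (S + t(S)) / 2                # enforce symmetry against round-off
  es <- eigen(S, symmetric = TRUE)
  U <- es$vectors / sp               # rows scaled: diag(1/sp) %*% V
  Uinv <- t(es$vectors * sp)         # t(diag(sp) %*% V)
  if (any(!is.finite(U)) || any(!is.finite(Uinv)))
    stop("numerically singular eigendecomposition of the rate matrix")
  structure(list(Q = Q, pi = pi, gtr = gtr, freqs = freqs,
                 values = es$values, vectors = U, inv_vectors = Uinv),
            class = "rate_matrix")
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' Computed from the eigendecomposition cached in the rate matrix. Entries
#' are clipped to be non-negative and rows renormalized against round-off.
#'
#' @param rm a [build_rate_matrix] object.
#' @param t branch length (expected substitutions per site, >= 0).
#' @param rate relative rate multiplier (> 0), e.g. a gamma category rate.
#' @return 4x4 row-stochastic matrix of state transition probabilities.
#' @export
transition_probabilities <- function(rm, t, rate = 1) {
  stopifnot(inherits(rm, "rate_matrix"))
  if (!is.finite(t) || t < 0) stop("'t' must be a non-negative branch length")
  if (!is.finite(rate) || rate <= 0) stop("'rate' must be positive")
  P <- rm$vectors %*% (exp(rm$values * t * rate) * rm$inv_vectors)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(rm$Q)
  P
}

#' One mixture class of the multitree mixture model
#'
#' Bundles a tree topology with branch lengths and its substitution model
#' components: GTR exchangeabilities, base frequencies and discrete-gamma
#' rate heterogeneity.
#'
#' @param tree a `phylo` tree (unrooted binary; branch lengths in
#'   substitutions/site).
#' @param gtr a [gtr_params] object.
#' @param freqs a [base_freqs] object.
#' @param rhas a [discretize_gamma] object.
#' @return an object of class `class_model`.
#' @export
class_model <- function(tree, gtr = gtr_params(), freqs = base_freqs(),
                        rhas = discretize_gamma(1, 1L)) {
  stopifnot(inherits(tree, "phylo"))
  if (!inherits(gtr, "gtr_params")) gtr <- gtr_params(gtr)
  if (!inherits(freqs, "base_freqs")) freqs <- base_freqs(freqs)
  stopifnot(inherits(rhas, "gamma_rhas"))
  structure(list(tree = tree, gtr = gtr, freqs = freqs, rhas = rhas),
            class = "class_model")
}
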