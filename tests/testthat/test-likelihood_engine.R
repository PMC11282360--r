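test_that("pruning matches exhaustive enumeration on small trees", {
  set.seed(10)
  for (i in 1:12) {
    nt <- sample(4:5, 1)
    cm <- rand_class_model(nt, ncat = sample(c(1L, 4L), 1))
    aln <- simulate_alignment(cm$tree, cm, 20)
    # splice in some gaps and ambiguity codes
    aln$states[1, 1:3] <- c(15L, 5L, 10L)
    paln <- compress_patterns(aln)
    ours <- class_site_log_likelihoods(paln, cm)
    oracle <- brute_force_site_logliks(cm$tree, cm, paln)
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
})

test_that("pruning is invariant to the arbitrary internal rooting", {
  set.seed(11)
  cm <- rand_class_model(6)
  aln <- simulate_alignment(cm$tree, cm, 50)
  paln <- compress_patterns(aln)
  base <- class_site_log_likelihoods(paln, cm)
  for (og in c("t2", "t5")) {
    tr <- ape::root(cm$tree, outgroup = og, resolve.root = TRUE)
    cm2 <- class_model(tr, cm$gtr, cm$freqs, cm$rhas)
    expect_equal(class_site_log_likelihoods(paln, cm2), base,
                 tolerance = 1e-9)
  }
})

test_that("near-zero branch lengths reduce a constant column to pi_x", {
  tr <- ape::read.tree(text = "((t1:1e-9,t2:1e-9):1e-9,t3:1e-9,t4:1e-9);")
  p <- draw_model_params()
  cm <- class_model(tr, p$gtr, p$freqs, discretize_gamma(1, 1L))
  aln <- mast_alignment(matrix("C", 4, 1, dimnames = list(paste0("t", 1:4), NULL)))
  ll <- class_site_log_likelihoods(compress_patterns(aln), cm)
  expect_equal(ll, log(unclass(p$freqs)[2]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mixture likelihood follows the weighted-sum formula", {
  logL <- cbind(log(2e-5), log(1e-5))
  expect_equal(mixture_site_likelihood(logL, c(0.25, 0.75)),
               log(0.25 * 2e-5 + 0.75 * 1e-5), tolerance = 1e-12)
  # single class returns the vector unchanged
  v <- matrix(c(-3.2, -7.1, -0.5), ncol = 1)
  expect_equal(mixture_site_likelihood(v, 1), as.numeric(v))
  # identical classes collapse to the single-class value for any weights
  L2 <- cbind(v, v)
  expect_equal(mixture_site_likelihood(L2, c(1 - 1e-6, 1e-6)), as.numeric(v),
               tolerance = 1e-9)
  expect_error(mixture_site_likelihood(L2, c(1, 1, 1) / 3), "class count")
  expect_error(mixture_site_likelihood(L2, c(1, 0)), "positive")
})

test_that("posterior assignment normalizes and matches hand computation", {
  logL <- cbind(log(2e-5), log(1e-5))
  p <- posterior_assignment(logL, c(0.25, 0.75))
  expect_equal(as.numeric(p), c(0.4, 0.6), tolerance = 1e-12)
  # symmetry: equal weights, equal likelihoods
  L <- matrix(log(1e-4), 5, 3)
  p3 <- posterior_assignment(L, rep(1 / 3, 3))
  expect_equal(as.numeric(p3), rep(1 / 3, 15), tolerance = 1e-12)
  # weight approaching 1 concentrates all posteriors
  set.seed(12)
  L <- matrix(log(runif(10, 1e-6, 1e-4)), 5, 2)
  pf <- posterior_assignment(L, c(1 - 1e-6, 1e-6))
  expect_true(all(pf[, 1] > 0.99))
  expect_equal(rowSums(pf), rep(1, 5), tolerance = 1e-12)
})

test_that("total log-likelihood equals the uncompressed per-site sum", {
  set.seed(13)
  cm1 <- rand_class_model(5)
  cm2 <- class_model(draw_branch_lengths(rand_topo(5)), cm1$gtr, cm1$freqs,
                     cm1$rhas)
  aln <- simulate_alignment(cm1$tree, cm1, 100)
  paln <- compress_patterns(aln)
  w <- c(0.4, 0.6)
  logL <- cbind(class_site_log_likelihoods(paln, cm1),
                class_site_log_likelihoods(paln, cm2))
  tot <- total_log_likelihood(logL, w, paln$weights)
  # uncompressed: every site its own pattern
  persite <- mixture_site_likelihood(logL, w)[paln$site_map]
  expect_equal(tot, sum(persite), tolerance = 1e-9)
  # permuting columns leaves the total unchanged
  perm <- sample(aln$nsites)
  aln2 <- aln; aln2$states <- aln$states[, perm]
  paln2 <- compress_patterns(aln2)
  logL2 <- cbind(class_site_log_likelihoods(paln2, cm1),
                 class_site_log_likelihoods(paln2, cm2))
  expect_equal(total_log_likelihood(logL2, w, paln2$weights), tot,
               tolerance = 1e-9)
  # one pattern with weight N
  lone <- compress_patterns(mast_alignment(
    matrix("G", 5, 7, dimnames = list(paste0("t", 1:5), NULL))))
  lg <- cbind(class_site_log_likelihoods(lone, cm1))
  expect_equal(total_log_likelihood(lg, 1, lone$weights), 7 * as.numeric(lg))
})

test_that("expected class log-likelihood reduces correctly", {
  set.seed(14)
  clL <- log(runif(8, 1e-6, 1e-2))
  wts <- sample(1:5, 8, replace = TRUE)
  expect_equal(expected_class_log_likelihood(rep(1, 8), clL, wts),
               sum(wts * clL))
  expect_equal(expected_class_log_likelihood(rep(0, 8), clL, wts), 0)
  p <- runif(8)
  expect_equal(expected_class_log_likelihood(p, clL, wts),
               sum(wts * p * clL))
})

test_that("pattern compression never changes the class likelihood", {
  set.seed(15)
  cm <- rand_class_model(5)
  aln <- simulate_alignment(cm$tree, cm, 200)
  paln <- compress_patterns(aln)
  compressed <- sum(paln$weights * class_site_log_likelihoods(paln, cm))
  # uncompressed evaluation: pattern alignment with unit weights per site
  unc <- list(labels = aln$labels, states = aln$states,
              weights = rep(1L, aln$nsites),
              site_map = seq_len(aln$nsites), nsites = aln$nsites)
  class(unc) <- "pattern_alignment"
  expect_equal(sum(class_site_log_likelihoods(unc, cm)), compressed,
               tolerance = 1e-8)
})
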