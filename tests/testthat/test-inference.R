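test_that("free-parameter counts follow the stated counting rule", {
  expect_equal(count_free_parameters(6, 3, 4), 2 + 15 + 5 + 3 + 1)
  expect_equal(count_free_parameters(1, 2, 6), 1 + 18 + 10 + 6 + 2)
  # m = 1 equals the single-tree model regardless of submodel
  for (s in 1:6)
    expect_equal(count_free_parameters(s, 1, 8), (2 * 8 - 3) + 5 + 3 + 1)
  expect_error(count_free_parameters(7, 2, 4), "1..6")
})

test_that("submodel linkage encodes the six-model hierarchy", {
  lks <- lapply(1:6, submodel_linkage)
  expect_equal(vapply(lks, `[[`, TRUE, "sub"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(vapply(lks, `[[`, TRUE, "freq"),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(vapply(lks, `[[`, TRUE, "rhas"),
               c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  # the linked-substitution/unlinked-frequency combinations are absent
  for (lk in lks) expect_false(lk$sub && !lk$freq)
})

test_that("BIC arithmetic and ordering", {
  expect_equal(bic(-1000, 5, 100), 2000 + 5 * log(100))
  expect_true(bic(-1000, 6, 100) > bic(-1000, 5, 100))
  expect_true(bic(-990, 5, 100) < bic(-1000, 5, 100))
  expect_error(bic(-10, 2, 0), "nsites")
})

test_that("fits are monotone, converge, and expose coherent accessors", {
  set.seed(30)
  # well-separated two-class mixture so the fit converges briskly
  t1 <- rand_topo(6)
  t2 <- random_spr_neighbors(t1, k = 3, count = 1)[[1]]
  p1 <- draw_model_params(); p2 <- draw_model_params()
  classes <- list(
    class_model(draw_branch_lengths(t1), p1$gtr, p1$freqs,
                discretize_gamma(p1$alpha, 4L)),
    class_model(draw_branch_lengths(t2), p2$gtr, p2$freqs,
                discretize_gamma(p2$alpha, 4L)))
  d <- simulate_mixture(mixture_sim_spec(classes, weights = c(0.6, 0.4),
                                         length = 2000, mode = "block"))
  fit <- mast(d$alignment, list(t1, t2), submodel = 1, epsilon = 1e-3)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-6 * abs(fit$logLik)))
  expect_lt(fit$trace[length(fit$trace)] - fit$trace[length(fit$trace) - 1],
            fit$epsilon)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weights >= fit$weight_floor))
  expect_equal(rowSums(fit$posteriors), rep(1, fit$npatterns), tolerance = 1e-9)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), count_free_parameters(1, 2, 6))
  expect_equal(BIC(ll), fit$BIC, tolerance = 1e-9)
  co <- coef(fit)
  expect_true(all(c("w1", "w2", "c1.rAC", "c2.piT", "c1.alpha") %in% names(co)))
  pr <- predict(fit)
  expect_equal(nrow(pr), d$alignment$nsites)
  expect_equal(rowSums(pr[, c("p1", "p2")]), rep(1, nrow(pr)), tolerance = 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.mast_fit")
  expect_output(print(s), "Per-class")
})

test_that("single-class fit matches an independent ML fit (phangorn)", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  for (i in 1:3) {
    cm <- rand_class_model(5)
    aln <- simulate_alignment(cm$tree, cm, 800)
    paln <- compress_patterns(aln)
    fit <- mast_single_tree(aln, cm$tree, epsilon = 1e-6)
    pd <- as_phyDat(paln)
    # the independent evaluator agrees with ours at the fitted parameters
    eval_ph <- phangorn::pml(fit$trees[[1]], pd, k = 4,
                             bf = as.numeric(fit$freqs[[1]]),
                             Q = as.numeric(fit$gtr[[1]]),
                             shape = fit$alpha[1])
    expect_equal(fit$logLik, as.numeric(eval_ph$logLik), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # and its own independent fit does not beat ours
    pfit <- phangorn::optim.pml(
      phangorn::pml(ape::unroot(cm$tree), pd, k = 4),
      optEdge = TRUE, optBf = TRUE, optQ = TRUE, optGamma = TRUE,
      control = phangorn::pml.control(epsilon = 1e-9, maxit = 50, trace = 0))
    expect_gt(fit$logLik, as.numeric(pfit$logLik) - 1e-3)
  }
})

test_that("duplicate topologies are rejected unless allowed, and the
           degenerate duplicate mixture matches the single tree", {
  set.seed(32)
  cm <- rand_class_model(5)
  aln <- simulate_alignment(cm$tree, cm, 600)
  tr2 <- ape::root(cm$tree, outgroup = "t3", resolve.root = TRUE)
  expect_error(mast(aln, list(cm$tree, tr2)), "same unrooted topology")
  fit2 <- mast(aln, list(cm$tree, tr2), submodel = 6, allow_duplicates = TRUE)
  fit1 <- mast_single_tree(aln, cm$tree)
  expect_equal(fit2$logLik, fit1$logLik, tolerance = 1e-2)
})

test_that("data from a single tree give that tree nearly all the weight", {
  set.seed(33)
  cm <- rand_class_model(6)
  aln <- simulate_alignment(cm$tree, cm, 4000)
  other <- random_spr_neighbors(cm$tree, k = 2, count = 1)[[1]]
  fit <- mast(aln, list(cm$tree, other), submodel = 6)
  expect_gt(fit$weights[1], 0.85)
})

test_that("JC-simulated data recover near-unit exchangeabilities", {
  set.seed(34)
  tr <- draw_branch_lengths(rand_topo(6))
  cm <- class_model(tr, gtr_params(), base_freqs(), discretize_gamma(1, 1L))
  aln <- simulate_alignment(tr, cm, 8000)
  fit <- mast_single_tree(aln, tr, ncat = 1)
  expect_equal(unname(unclass(fit$gtr[[1]])), rep(1, 6), tolerance = 0.25)
  expect_equal(unname(unclass(fit$freqs[[1]])), rep(0.25, 4), tolerance = 0.03)
})
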