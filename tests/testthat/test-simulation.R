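test_that("alignment simulation has the right shape and is seed-reproducible", {
  set.seed(40)
  cm <- rand_class_model(6)
  a1 <- simulate_alignment(cm$tree, cm, 123, seed = 99)
  expect_equal(a1$nsites, 123L)
  expect_setequal(a1$labels, cm$tree$tip.label)
  a2 <- simulate_alignment(cm$tree, cm, 123, seed = 99)
  expect_identical(a1$states, a2$states)
  a3 <- simulate_alignment(cm$tree, cm, 123, seed = 100)
  expect_false(identical(a1$states, a3$states))
})

test_that("very long branches drive tip composition to the frequencies", {
  tr <- ape::read.tree(text = "((t1:50,t2:50):50,t3:50,t4:50);")
  f <- c(0.4, 0.1, 0.2, 0.3)
  cm <- class_model(tr, gtr_params(), base_freqs(f), discretize_gamma(1, 1L))
  a <- simulate_alignment(tr, cm, 20000, seed = 41)
  for (i in 1:4) {
    obs <- tabulate(log2(a$states[i, ]) + 1, 4) / a$nsites
    se <- sqrt(f * (1 - f) / a$nsites)
    expect_true(all(abs(obs - f) < 3.5 * se))
  }
})

test_that("mixture simulation: block labels, iid proportions, degenerate case", {
  set.seed(42)
  cms <- list(rand_class_model(5), rand_class_model(5))
  cms[[2]]$tree$tip.label <- cms[[1]]$tree$tip.label
  spec <- mixture_sim_spec(cms, block_lengths = c(45, 35), length = 80,
                           mode = "block")
  sim <- simulate_mixture(spec)
  expect_equal(sim$labels, rep(1:2, c(45, 35)))
  expect_equal(sim$alignment$nsites, 80L)

  spec2 <- mixture_sim_spec(cms, weights = c(0.5, 0.5), length = 20000,
                            mode = "iid")
  sim2 <- simulate_mixture(spec2, seed = 43)
  frac <- mean(sim2$labels == 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 20000))

  expect_error(mixture_sim_spec(cms, block_lengths = c(45, 36), length = 80,
                                mode = "block"), "sum")
})

test_that("random SPR moves change the topology by the expected amount", {
  skip_if_not_installed("phangorn")
  set.seed(44)
  tr <- rand_topo(8)
  nb <- random_spr_neighbors(tr, k = 1, count = 5)
  for (t2 in nb) {
    expect_false(topology_id(t2) == topology_id(tr))
    rf <- phangorn::RF.dist(ape::unroot(tr), ape::unroot(t2))
    expect_gte(rf, 2)
    expect_equal(as.numeric(phangorn::SPR.dist(ape::unroot(tr),
                                               ape::unroot(t2))), 1)
  }
  # pairwise distinct when requested
  ids <- vapply(nb, topology_id, "")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("random 1-SPR draws cover exactly the enumerated neighborhood", {
  set.seed(45)
  all15 <- all_topologies_5taxa()
  src <- all15[[4]]
  nbhd <- spr_neighbors(src)
  oracle_ids <- sort(vapply(nbhd, topology_id, ""))
  # neighborhood size of an unrooted binary tree: 2(n-3)(2n-7)
  expect_length(oracle_ids, 2 * (5 - 3) * (2 * 5 - 7))
  got <- character(0)
  for (i in 1:200) {
    got <- union(got,
                 topology_id(random_spr_neighbors(src, k = 1, count = 1,
                                                  distinct = FALSE)[[1]]))
  }
  expect_identical(sort(got), oracle_ids)
})

test_that("k-SPR neighbors of 6-tip trees stay within 2 SPR moves", {
  set.seed(46)
  tr <- rand_topo(6)
  lvl1 <- vapply(spr_neighbors(tr), topology_id, "")
  lvl2 <- unique(c(lvl1, unlist(lapply(spr_neighbors(tr), function(t1)
    vapply(spr_neighbors(t1), topology_id, "")))))
  for (k in 1:3) {
    nb <- random_spr_neighbors(tr, k = k, count = 3)
    expect_true(all(vapply(nb, topology_id, "") %in% lvl2))
  }
})

test_that("requesting more distinct neighbors than exist fails cleanly", {
  set.seed(47)
  tr <- rand_topo(4)      # only 2 other unrooted topologies exist
  expect_error(random_spr_neighbors(tr, k = 1, count = 5), "exhausted")
})

test_that("all 15 five-taxon topologies are generated and distinct", {
  all15 <- all_topologies_5taxa()
  expect_length(all15, 15L)
  expect_equal(anyDuplicated(vapply(all15, topology_id, "")), 0L)
})

test_that("coalescent gene trees match the analytic MSC expectation at r = 0", {
  spec <- introgression_spec(0, genes = 4000)
  gt <- sample_introgression_gene_trees(spec, seed = 48)
  topo <- attr(gt, "topology")
  p <- prop.table(table(factor(topo, levels = c("TE1", "TE2", "TE3"))))
  minor <- exp(-0.5) / 3            # internal branch 0.5 coalescent units
  se <- sqrt(minor * (1 - minor) / 4000)
  expect_lt(abs(p["TE2"] - minor), 3.5 * se)
  expect_lt(abs(p["TE3"] - minor), 3.5 * se)
  expect_gt(p["TE1"], p["TE2"])
  # minor-tree symmetry
  expect_lt(abs(p["TE2"] - p["TE3"]), 4 * se)
})

test_that("the introgression-history topology becomes dominant as r grows", {
  fr <- vapply(c(0, 0.5, 1), function(r) {
    gt <- sample_introgression_gene_trees(introgression_spec(r, genes = 1500),
                                          seed = 49)
    mean(attr(gt, "topology") == "TE2")
  }, 0)
  expect_true(fr[1] < fr[2] && fr[2] < fr[3])
  gt1 <- sample_introgression_gene_trees(introgression_spec(1, genes = 1500),
                                         seed = 50)
  tt <- table(attr(gt1, "topology"))
  expect_equal(names(which.max(tt)), "TE2")
})

test_that("gene rescaling and concatenation have the stated geometry", {
  set.seed(51)
  gt <- sample_introgression_gene_trees(introgression_spec(0.3, genes = 10),
                                        seed = 52)
  p <- draw_model_params()
  cm <- class_model(gt[[1]], p$gtr, p$freqs, discretize_gamma(p$alpha, 4L))
  sim <- rescale_and_simulate_genes(gt, cm, factor = 0.002, gene_length = 100)
  expect_equal(sim$alignment$nsites, 1000L)
  expect_equal(sim$labels, rep(1:10, each = 100))
  expect_length(attr(sim, "topology"), 1000L)
  # factor 0 gives identical sequences
  sim0 <- rescale_and_simulate_genes(gt, cm, factor = 0, gene_length = 50)
  st <- sim0$alignment$states
  expect_true(all(st == st[rep(1, nrow(st)), ]))
})

test_that("weight RMSE matches direct computation", {
  expect_equal(weight_rmse(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(weight_rmse(c(0.5, 0.5), c(0.6, 0.4)), 0.1)
  set.seed(53)
  for (i in 1:5) {
    a <- runif(4); b <- runif(4)
    expect_equal(weight_rmse(a, b), sqrt(mean((a - b)^2)))
  }
  expect_error(weight_rmse(c(1, 0), c(1, 0, 0)), "length")
})
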