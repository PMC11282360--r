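test_that("Fitch scores match hand examples and brute force", {
  tr <- ape::read.tree(text = "((a1,a2),(c1,c2));")
  aln <- aln_from_strings(a1 = "AA", a2 = "AC", c1 = "CC", c2 = "CC")
  paln <- compress_patterns(aln)
  # column 1 (AACC on ((a1,a2),(c1,c2))): one change on the internal edge;
  # column 2 (ACCC): one change on a terminal edge
  expect_equal(fitch_scores(paln, tr)[paln$site_map], c(1L, 1L))
  # constant column
  cons <- compress_patterns(aln_from_strings(a1 = "G", a2 = "G", c1 = "G", c2 = "G"))
  expect_equal(fitch_scores(cons, tr), 0L)
  # random 5-taxon columns vs exhaustive minimization, with ambiguity codes
  set.seed(20)
  tr5 <- rand_topo(5)
  for (i in 1:15) {
    col <- sample(c(1L, 2L, 4L, 8L, 15L, 5L), 5, replace = TRUE,
                  prob = c(rep(0.22, 4), 0.06, 0.06))
    names(col) <- tr5$tip.label
    st <- matrix(col, ncol = 1, dimnames = list(names(col), NULL))
    paln5 <- structure(list(labels = names(col), states = st,
                            weights = 1L, site_map = 1L, nsites = 1L),
                       class = "pattern_alignment")
    expect_equal(fitch_scores(paln5, tr5), brute_force_fitch(tr5, col))
  }
})

test_that("parsimony branch lengths conserve total changes and floor", {
  set.seed(21)
  cm <- rand_class_model(6)
  aln <- simulate_alignment(cm$tree, cm, 300)
  paln <- compress_patterns(aln)
  out <- parsimony_branch_lengths(paln, cm$tree, min_bl = 1e-6)
  total_score <- sum(paln$weights * fitch_scores(paln, cm$tree))
  expect_equal(attr(out, "total_changes"), total_score)
  # lengths are changes per site (before flooring), so they sum to score/N
  expect_equal(sum(out$edge.length[out$edge.length > 1e-6]),
               total_score / paln$nsites, tolerance = 1e-6)
  # identical sequences: every branch at the floor
  same <- compress_patterns(mast_alignment(
    matrix(rep(c("A", "C", "G"), each = 6), 6, 3,
           dimnames = list(paste0("t", 1:6), NULL))))
  fl <- parsimony_branch_lengths(same, cm$tree, min_bl = 1e-6)
  expect_true(all(fl$edge.length == 1e-6))
  # a single discriminating site class maps onto the internal branch
  tr <- ape::read.tree(text = "((a1,a2),(c1,c2));")
  aln2 <- aln_from_strings(a1 = "AAAAAAAACA", a2 = "AAAAAAAACA",
                           c1 = "CAAAAAAACA", c2 = "CAAAAAAACA")
  pb <- parsimony_branch_lengths(compress_patterns(aln2), tr)
  internal <- pb$edge.length[pb$edge[, 2] > 4]
  expect_equal(internal, 1 / 10, tolerance = 1e-9)
})

test_that("parsimony weight initialization assigns discriminating sites", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  # 30 sites favoring t1 (ab|cd pattern), 10 favoring t2 (ac|bd), 20 constant
  s1 <- c(a = "A", b = "A", c = "C", d = "C")
  s2 <- c(a = "A", b = "C", c = "A", d = "C")
  s0 <- c(a = "G", b = "G", c = "G", d = "G")
  mk <- function(counts) {
    cols <- cbind(matrix(rep(s1, counts[1]), 4),
                  matrix(rep(s2, counts[2]), 4),
                  matrix(rep(s0, counts[3]), 4))
    rownames(cols) <- names(s1)
    compress_patterns(mast_alignment(cols))
  }
  w <- initialize_weights(mk(c(30, 10, 20)), list(t1, t2))
  expect_equal(w, c(0.75, 0.25), tolerance = 1e-9)
  # no discriminating sites: equal weights
  expect_equal(initialize_weights(mk(c(0, 0, 20)), list(t1, t2)), c(0.5, 0.5))
  # three trees where the minimum is shared: the site splits fractionally
  # and totals conserve the discriminating-site count
  t3 <- ape::read.tree(text = "((a,d),(b,c));")
  paln <- mk(c(12, 6, 10))
  w3 <- initialize_weights(paln, list(t1, t2, t3))
  S <- vapply(list(t1, t2, t3), function(tr) fitch_scores(paln, tr),
              integer(length(paln$weights)))
  disc <- apply(S, 1, function(r) min(r) < max(r))
  expect_equal(sum(w3) , 1, tolerance = 1e-12)
  # reconstruct absolute contributions: weights * discriminating-site count
  expect_equal(sum(paln$weights[disc]), 18)
  expect_true(w3[1] > w3[2])
})
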