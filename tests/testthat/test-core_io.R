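test_that("FASTA and relaxed PHYLIP readers agree and validate input", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "acgtacgtnc",
               ">c", "ACG-ACGTAC", ">d", "ACGTACGTAg"), fa)
  a1 <- read_alignment(fa, "fasta")
  expect_equal(length(a1$labels), 4L)
  expect_equal(a1$nsites, 10L)

  ph <- tempfile(fileext = ".phy")
  writeLines(c("4 10", "a ACGTACGTAC", "b ACGTACGTNC",
               "c ACG-ACGTAC", "d ACGTACGTAG"), ph)
  a2 <- read_alignment(ph, "phylip")
  expect_identical(a1$states, a2$states)

  # wrapped sequences in the phylip body
  ph2 <- tempfile(fileext = ".phy")
  writeLines(c("2 10", "a ACGTA", "CGTAC", "b ACGTACGTAC"), ph2)
  a3 <- read_alignment(ph2, "phylip")
  expect_equal(a3$nsites, 10L)

  # ragged record is reported by name
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA", ">c", "ACGTACGTAC"), bad)
  expect_error(read_alignment(bad, "fasta"), "'b'")

  # duplicate labels rejected
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_alignment(dup, "fasta"), "duplicate")

  # unknown character named with its record (constructor-level check; the
  # FASTA reader's DNA decoding cannot emit unknown characters)
  expect_error(mast_alignment(c(a = "ACGT", b = "ACXT")), "X")

  expect_error(read_alignment(tempfile(), "fasta"), "not found")
})

test_that("U maps to T, case folds, and all-gap columns are dropped", {
  a <- mast_alignment(c(x = "acgu", y = "ACGT"))
  expect_identical(a$states["x", ], a$states["y", ])
  expect_message(b <- mast_alignment(c(x = "A-G", y = "A-G")), "1 all-gap")
  expect_equal(b$nsites, 2L)
})

test_that("alignment FASTA round-trip preserves states", {
  a <- aln_from_strings(t1 = "ACGTRYN-AC", t2 = "ACGTACGTAC", t3 = "TTTTACGWAC")
  f <- tempfile(fileext = ".fasta")
  write_alignment(a, f)
  b <- read_alignment(f, "fasta")
  expect_identical(a$states, b$states[a$labels, ])
})

test_that("pattern compression is lossless and weight-conserving", {
  set.seed(1)
  cm <- rand_class_model(5)
  aln <- simulate_alignment(cm$tree, cm, 100)
  paln <- compress_patterns(aln)
  expect_equal(sum(paln$weights), aln$nsites)
  expect_identical(mastr:::expand_patterns(paln)$states, aln$states)

  one <- mast_alignment(matrix("A", 4, 6,
                               dimnames = list(paste0("t", 1:4), NULL)))
  pone <- compress_patterns(one)
  expect_equal(length(pone$weights), 1L)
  expect_equal(pone$weights, 6L)

  # all-distinct columns: pattern count equals site count
  dis <- mast_alignment(rbind(t1 = c("A", "C", "G"), t2 = c("C", "G", "A"),
                              t3 = c("G", "A", "C"), t4 = c("T", "T", "A")))
  expect_equal(length(compress_patterns(dis)$weights), 3L)
})

test_that("canonical topology identifiers detect unrooted equality", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "(c,(d,(b,a)));")       # same unrooted topology
  t3 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_identical(topology_id(t1), topology_id(t2))
  expect_false(topology_id(t1) == topology_id(t3))
  # invariant to rooting and rotation for random trees
  set.seed(2)
  for (i in 1:10) {
    tr <- rand_topo(7)
    rr <- ape::root(tr, outgroup = sample(tr$tip.label, 1), resolve.root = TRUE)
    expect_identical(topology_id(tr), topology_id(rr))
  }
})

test_that("tree reading validates tips, shape and duplicates", {
  tf <- tempfile(fileext = ".nwk")
  writeLines(c("((t1,t2),(t3,t4),t5);", "((t1,t3),(t2,t4),t5);",
               "((t1,t4),(t2,t3),t5);"), tf)
  trs <- read_trees(tf, paste0("t", 1:5))
  expect_length(trs, 3L)
  expect_error(read_trees(tf, paste0("t", 1:4)), "mismatch")

  dupf <- tempfile(fileext = ".nwk")
  writeLines(c("((t1,t2),(t3,t4));", "(t3,(t4,(t2,t1)));"), dupf)
  expect_error(read_trees(dupf, paste0("t", 1:4)), "same unrooted topology")
  expect_length(read_trees(dupf, paste0("t", 1:4), allow_duplicates = TRUE), 2L)

  nb <- tempfile(fileext = ".nwk")
  writeLines("((t1,t2,t3),(t4,t5),t6);", nb)
  expect_error(read_trees(nb, paste0("t", 1:6)), "binary")

  # round trip
  out <- tempfile(fileext = ".nwk")
  write_trees(trs, out)
  back <- read_trees(out, paste0("t", 1:5))
  expect_identical(vapply(trs, topology_id, ""), vapply(back, topology_id, ""))
})
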