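# Trees are ape "phylo" objects, treated as unrooted binary topologies.
# Internally they are stored with an arbitrary (trifurcating) root; all
# likelihood computations are invariant to that rooting under reversible
# models (pulley principle).

# Standardize a tree for internal use: unrooted, postorder-indexable.
standardize_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.rooted(tree) && length(tree$tip.label) >= 3L) tree <- ape::unroot(tree)
  tree
}

is_binary_unrooted <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- standardize_tree(tree)
  nrow(tr$edge) == 2L * nt - 3L && tr$Nnode == nt - 2L
}

#' Canonical topology identifier
#'
#' A string identifying the unrooted topology, invariant to tip order,
#' rooting and rotations: the sorted list of non-trivial splits, each split
#' written as the sorted tip labels on the side not containing the
#' lexicographically smallest tip. Two trees have equal identifiers iff their
#' unrooted split sets are equal.
#'
#' @param tree a `phylo` object.
#' @return character scalar.
#' @export
topology_id <- function(tree) {
  tree <- standardize_tree(tree)
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  if (nt < 4L) return(paste(sort(tree$tip.label), collapse = ","))
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode_total <- nt + tr$Nnode
  desc <- vector("list", nnode_total)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  splits <- character(0)
  all_tips <- sort(tree$tip.label)
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 2L]
    if (v <= nt) next                       # trivial split
    side <- desc[[v]]
    if (ref %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > nt - 2L) next
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  paste(sort(unique(splits)), collapse = "|")
}

#' Read a set of tree topologies
#'
#' Reads Newick trees (one per line) and validates them against the taxa of
#' an alignment: every tree must be a binary unrooted topology on exactly the
#' required tip set. Trees without branch lengths are given a placeholder
#' length (initial branch lengths are replaced by parsimony-based values when
#' fitting anyway). Duplicate unrooted topologies are rejected by default
#' because a mixture of identical topologies is not identifiable in the tree
#' weights.
#'
#' @param path Newick file, one tree per line.
#' @param required_tips character vector of taxon labels the trees must carry
#'   (e.g. `aln$labels`); `NULL` skips the check (tip sets must still agree
#'   across trees).
#' @param allow_duplicates keep duplicate topologies instead of rejecting
#'   them (useful for branch-length-mixture degenerate cases).
#' @return a `multiPhylo` list of trees, in file order.
#' @export
read_trees <- function(path, required_tips = NULL, allow_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("no trees could be parsed from ", path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  validate_trees(trees, required_tips, allow_duplicates)
}

# Shared validation for trees supplied from file or constructed in code.
validate_trees <- function(trees, required_tips = NULL, allow_duplicates = FALSE) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  trees <- lapply(trees, standardize_tree)
  if (is.null(required_tips)) required_tips <- trees[[1L]]$tip.label
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    extra <- setdiff(tr$tip.label, required_tips)
    missing <- setdiff(required_tips, tr$tip.label)
    if (length(extra) || length(missing))
      stop("tree ", k, ": tip set mismatch (unmatched: ",
           paste(c(extra, missing), collapse = ", "), ")")
    if (!is_binary_unrooted(tr))
      stop("tree ", k, " is not a binary (fully resolved) unrooted topology")
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
    tr$edge.length[!is.finite(tr$edge.length)] <- 0.1
    trees[[k]] <- tr
  }
  ids <- vapply(trees, topology_id, "")
  if (!allow_duplicates && anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1L]
    stop("trees ", match(ids[d], ids), " and ", d,
         " encode the same unrooted topology; set allow_duplicates = TRUE to keep them")
  }
  structure(trees, class = "multiPhylo")
}

#' Write trees to a Newick file, one per line
#'
#' @param trees a `phylo` or `multiPhylo` object.
#' @param path output file.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  ape::write.tree(trees, file = path)
  invisible(path)
}
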