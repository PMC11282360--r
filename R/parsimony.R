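# Fitch parsimony over site patterns, used only for initialization: per-tree
# pattern scores drive the starting tree weights, and a minimal Fitch
# reconstruction attributes state changes to branches for starting branch
# lengths.  The unrooted tree is rooted on the edge to its first tip so that
# every internal node is binary and the Fitch score/traceback is exact.

lowest_bit <- function(x) bitwAnd(x, -x)

# Bottom-up Fitch pass on a binary rooted tree; returns state-set matrix
# (nodes x patterns), per-pattern scores, and the reordered tree.
fitch_down <- function(paln, tree) {
  tr <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1L],
                  resolve.root = TRUE)
  tr <- ape::reorder.phylo(tr, "postorder")
  nt <- length(tr$tip.label)
  npat <- ncol(paln$states)
  nnode_total <- nt + tr$Nnode
  sets <- matrix(0L, nnode_total, npat)
  sets[seq_len(nt), ] <- paln$states[match(tr$tip.label, paln$labels), , drop = FALSE]
  score <- integer(npat)
  seen <- logical(nnode_total)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    if (!seen[u]) {
      sets[u, ] <- sets[v, ]
      seen[u] <- TRUE
    } else {
      ii <- bitwAnd(sets[u, ], sets[v, ])
      un <- ii == 0L
      score <- score + un
      sets[u, ] <- ifelse(un, bitwOr(sets[u, ], sets[v, ]), ii)
    }
  }
  list(tree = tr, sets = sets, score = score, ntip = nt)
}

#' Fitch parsimony scores of every site pattern on a tree
#'
#' Minimum number of state changes required on the (unrooted) tree for each
#' site pattern; ambiguity codes and gaps count as their compatible state
#' sets.
#'
#' @param paln a [compress_patterns] pattern alignment.
#' @param tree a `phylo` topology on the alignment taxa.
#' @return integer vector, one score per pattern.
#' @export
fitch_scores <- function(paln, tree) {
  stopifnot(inherits(paln, "pattern_alignment"))
  fitch_down(paln, tree)$score
}

# Edge split keys (sorted child-side tip labels, canonicalized as in
# topology_id) used to map rooted-tree edges back to the unrooted tree.
edge_split_keys <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  ref <- sort(tr$tip.label)[1L]
  all_tips <- sort(tr$tip.label)
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    desc[[tr$edge[e, 1L]]] <- c(desc[[tr$edge[e, 1L]]], desc[[tr$edge[e, 2L]]])
  keys <- character(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    side <- desc[[tr$edge[e, 2L]]]
    if (ref %in% side) side <- setdiff(all_tips, side)
    keys[e] <- paste(sort(side), collapse = ",")
  }
  list(tree = tr, keys = keys)
}

#' Parsimony starting branch lengths
#'
#' Branch lengths initialized as state changes per site: one minimal Fitch
#' reconstruction is computed, the changes it implies are attributed to
#' branches, summed over sites (pattern-weighted), and divided by the number
#' of sites, with a floor at `min_bl`. The total attributed changes equal the
#' tree's total Fitch score.
#'
#' @inheritParams fitch_scores
#' @param min_bl minimum branch length.
#' @return the tree with `edge.length` replaced by the parsimony lengths.
#' @export
parsimony_branch_lengths <- function(paln, tree, min_bl = 1e-6) {
  fd <- fitch_down(paln, tree)
  tr <- fd$tree
  npat <- ncol(paln$states)
  E <- nrow(tr$edge)
  root <- tr$edge[E, 1L]
  state <- matrix(0L, fd$ntip + tr$Nnode, npat)
  state[root, ] <- lowest_bit(fd$sets[root, ])
  changes <- numeric(E)
  for (e in rev(seq_len(E))) {           # preorder: parents before children
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    keep <- bitwAnd(fd$sets[v, ], state[u, ])
    chg <- keep == 0L
    state[v, ] <- ifelse(chg, lowest_bit(fd$sets[v, ]), keep)
    changes[e] <- sum(paln$weights * chg)
  }
  # map the rooted edges (2t-2) onto the unrooted edges (2t-3): the two edges
  # at the artificial root share one unrooted split and their changes add
  rooted <- edge_split_keys(tr)
  target <- edge_split_keys(standardize_tree(tree))
  out <- target$tree
  bl <- numeric(nrow(out$edge))
  for (e in seq_len(E)) {
    idx <- which(target$keys == rooted$keys[e])
    if (length(idx) != 1L) stop("internal error: edge split mismatch")
    bl[idx] <- bl[idx] + changes[e]
  }
  out$edge.length <- pmax(bl / paln$nsites, min_bl)
  attr(out, "total_changes") <- sum(changes)
  out
}

#' Parsimony-based starting tree weights
#'
#' Sites whose Fitch parsimony scores differ between the candidate trees are
#' assigned to the tree(s) achieving the minimum score (split fractionally on
#' ties); the starting weights are the resulting assigned-site proportions.
#' If no site discriminates, weights are equal. Weights are floored and
#' renormalized.
#'
#' @param paln a [compress_patterns] pattern alignment.
#' @param trees a list/`multiPhylo` of candidate topologies.
#' @param weight_floor minimum weight.
#' @return numeric weight vector (one per tree, positive, summing to 1).
#' @export
initialize_weights <- function(paln, trees, weight_floor = 1e-6) {
  m <- length(trees)
  if (m == 1L) return(1)
  S <- vapply(trees, function(tr) fitch_scores(paln, tr), integer(ncol(paln$states)))
  rmin <- do.call(pmin, as.data.frame(S))
  rmax <- do.call(pmax, as.data.frame(S))
  disc <- rmin < rmax
  if (!any(disc)) {
    w <- rep(1 / m, m)
  } else {
    win <- S[disc, , drop = FALSE] == rmin[disc]
    contrib <- (paln$weights[disc] / rowSums(win)) * win
    w <- colSums(contrib)
    if (sum(w) == 0) w <- rep(1 / m, m) else w <- w / sum(w)
  }
  w <- pmax(w, weight_floor)
  w / sum(w)
}
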