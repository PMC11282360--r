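# Simulators: alignments under a single class or a tree mixture, random
# SPR-perturbed topologies, and 4-taxon coalescent gene trees with a single
# introgression pulse.  All simulators are plain R; reproducibility comes
# from R's RNG (set a seed before calling, or pass `seed`).

#' Simulate an alignment on one tree under GTR+G
#'
#' Root states are drawn from the stationary frequencies, each site gets an
#' independent gamma-category rate, and states evolve down every branch via
#' the transition probabilities.
#'
#' @param tree a `phylo` with branch lengths (substitutions/site).
#' @param cm a [class_model] supplying GTR, frequencies, and rate
#'   heterogeneity (the tree inside `cm` is ignored).
#' @param length number of sites.
#' @param seed optional RNG seed.
#' @return a [mast_alignment].
#' @export
simulate_alignment <- function(tree, cm, length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"), inherits(cm, "class_model"), length >= 1)
  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  rm <- build_rate_matrix(cm$gtr, cm$freqs)
  rates <- cm$rhas$rates
  K <- length(rates)
  nt <- length(tr$tip.label)
  ntot <- nt + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1L]
  state <- matrix(0L, ntot, length)
  state[root, ] <- sample.int(4L, length, replace = TRUE, prob = rm$pi)
  cat_k <- sample.int(K, length, replace = TRUE)
  for (e in rev(seq_len(nrow(tr$edge)))) {       # preorder
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    t <- tr$edge.length[e]
    for (k in seq_len(K)) {
      P <- transition_probabilities(rm, t, rates[k])
      for (s in 1:4) {
        idx <- which(state[u, ] == s & cat_k == k)
        if (length(idx))
          state[v, idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
  }
  st <- matrix(2L^(state[seq_len(nt), , drop = FALSE] - 1L), nrow = nt,
               dimnames = list(tr$tip.label, NULL))
  structure(list(labels = tr$tip.label, states = st, nsites = length),
            class = "mast_alignment")
}

#' Specification of a tree-mixture simulation
#'
#' @param classes list of [class_model]s (trees with branch lengths).
#' @param weights class proportions (iid mode); must sum to 1.
#' @param block_lengths per-class block lengths (block mode); must sum to
#'   `length`.
#' @param length total alignment length.
#' @param mode `"block"` concatenates one region per class in order (as when
#'   distinct genomic regions follow distinct histories); `"iid"` draws each
#'   site's class independently from the weights.
#' @return an object of class `mixture_sim_spec`.
#' @export
mixture_sim_spec <- function(classes, weights = NULL, block_lengths = NULL,
                             length, mode = c("iid", "block")) {
  mode <- match.arg(mode)
  stopifnot(is.list(classes), length(classes) >= 1L)
  m <- base::length(classes)
  if (mode == "block") {
    if (is.null(block_lengths) && !is.null(weights))
      block_lengths <- diff(round(cumsum(c(0, weights)) * length))
    stopifnot(base::length(block_lengths) == m)
    if (sum(block_lengths) != length)
      stop("block lengths must sum to the total length")
  } else {
    stopifnot(!is.null(weights), base::length(weights) == m)
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  }
  structure(list(classes = classes, weights = weights,
                 block_lengths = block_lengths, length = length, mode = mode),
            class = "mixture_sim_spec")
}

#' Simulate an alignment under a tree mixture
#'
#' @param spec a [mixture_sim_spec].
#' @param seed optional RNG seed.
#' @return list with `alignment` (a [mast_alignment]) and `labels` (integer
#'   class index per site).
#' @export
simulate_mixture <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "mixture_sim_spec"))
  m <- length(spec$classes)
  N <- spec$length
  if (spec$mode == "block") {
    labels <- rep.int(seq_len(m), spec$block_lengths)
  } else {
    labels <- sample.int(m, N, replace = TRUE, prob = spec$weights)
  }
  first <- spec$classes[[1L]]$tree$tip.label
  states <- matrix(0L, length(first), N)
  for (j in seq_len(m)) {
    idx <- which(labels == j)
    if (!length(idx)) next
    a <- simulate_alignment(spec$classes[[j]]$tree, spec$classes[[j]],
                            length(idx))
    states[, idx] <- a$states[match(first, a$labels), , drop = FALSE]
  }
  rownames(states) <- first
  list(alignment = structure(list(labels = first, states = states, nsites = N),
                             class = "mast_alignment"),
       labels = labels)
}

# --- subtree prune and regraft ---------------------------------------------

adj_from_tree <- function(tree) {
  tr <- standardize_tree(tree)
  ntot <- length(tr$tip.label) + tr$Nnode
  adj <- vector("list", ntot)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  list(adj = adj, ntip = length(tr$tip.label), labels = tr$tip.label)
}

newick_from_adj <- function(g) {
  deg <- lengths(g$adj)
  root <- which(deg >= 3L)[1L]
  rec <- function(v, parent) {
    nb <- setdiff(g$adj[[v]], parent)
    if (!length(nb)) return(g$labels[v])
    paste0("(", paste(vapply(nb, rec, "", parent = v), collapse = ","), ")")
  }
  txt <- paste0("(", paste(vapply(g$adj[[root]], rec, "", parent = root),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

# One SPR move on the adjacency graph; returns the modified graph or NULL if
# the sampled prune direction admits no valid regraft edge.
spr_apply <- function(g, u, v, a, b) {
  adj <- g$adj
  # detach v-side from u, suppress u if it drops to degree 2
  adj[[u]] <- setdiff(adj[[u]], v)
  adj[[v]] <- setdiff(adj[[v]], u)
  if (length(adj[[u]]) == 2L) {
    nb <- adj[[u]]
    adj[[nb[1L]]] <- unique(c(setdiff(adj[[nb[1L]]], u), nb[2L]))
    adj[[nb[2L]]] <- unique(c(setdiff(adj[[nb[2L]]], u), nb[1L]))
    adj[[u]] <- integer(0)
  }
  # new attachment node w subdividing edge (a, b)
  w <- length(adj) + 1L
  adj[[a]] <- c(setdiff(adj[[a]], b), w)
  adj[[b]] <- c(setdiff(adj[[b]], a), w)
  adj[[w]] <- c(a, b, v)
  adj[[v]] <- c(adj[[v]], w)
  g$adj <- adj
  g$labels <- c(g$labels, rep(NA_character_, w - length(g$labels)))
  g
}

# candidate regraft edges for pruning the v-side of directed edge (u, v):
# all edges with both ends in the u-side component, not incident to u
spr_candidates <- function(g, u, v) {
  comp <- u
  frontier <- setdiff(g$adj[[u]], v)
  while (length(frontier)) {
    comp <- c(comp, frontier)
    frontier <- setdiff(unlist(g$adj[frontier]), comp)
  }
  inset <- logical(length(g$adj)); inset[comp] <- TRUE
  out <- list()
  for (a in comp) {
    if (a == u) next
    for (b in g$adj[[a]]) {
      if (b > a && b != u && inset[b]) out[[length(out) + 1L]] <- c(a, b)
    }
  }
  out
}

# a single uniform-random SPR move that changes the unrooted topology
spr_random_move <- function(tree) {
  g <- adj_from_tree(tree)
  deg <- lengths(g$adj)
  internal <- which(deg >= 3L)
  for (try in 1:100) {
    u <- internal[sample.int(length(internal), 1L)]
    v <- g$adj[[u]][sample.int(length(g$adj[[u]]), 1L)]
    cand <- spr_candidates(g, u, v)
    if (!length(cand)) next
    ab <- cand[[sample.int(length(cand), 1L)]]
    return(newick_from_adj(spr_apply(g, u, v, ab[1L], ab[2L])))
  }
  stop("could not find a valid SPR move")
}

#' Exhaustive 1-SPR neighborhood of a topology
#'
#' Enumerates every topology reachable by a single subtree
#' prune-and-regraft move (all directed prune edges times all valid regraft
#' edges), deduplicated by canonical topology identifier. The neighborhood
#' size of an unrooted binary tree on n tips is 2(n-3)(2n-7).
#'
#' @param tree a `phylo` topology (>= 4 tips).
#' @return a `multiPhylo` of distinct neighbor topologies.
#' @export
spr_neighbors <- function(tree) {
  g <- adj_from_tree(tree)
  deg <- lengths(g$adj)
  out <- list()
  seen <- character(0)
  for (u in which(deg >= 3L)) {
    for (v in g$adj[[u]]) {
      for (ab in spr_candidates(g, u, v)) {
        t2 <- newick_from_adj(spr_apply(g, u, v, ab[1L], ab[2L]))
        id <- topology_id(t2)
        if (!(id %in% seen)) { out[[length(out) + 1L]] <- t2; seen <- c(seen, id) }
      }
    }
  }
  structure(out, class = "multiPhylo")
}

#' Random SPR neighbor topologies
#'
#' Generates trees by applying k sequential uniform-random subtree
#' prune-and-regraft moves to the input topology. Every individual move
#' changes the unrooted topology (regrafting next to the original attachment
#' point is excluded), and every returned tree differs from the input
#' topology; with `distinct = TRUE` the returned trees are also pairwise
#' distinct.
#'
#' @param tree source `phylo` topology (>= 4 tips).
#' @param k number of sequential SPR moves per output tree.
#' @param count number of trees to generate.
#' @param seed optional RNG seed.
#' @param distinct require pairwise-distinct output topologies.
#' @return a `multiPhylo` of `count` topologies (no branch lengths).
#' @export
random_spr_neighbors <- function(tree, k = 1L, count = 1L, seed = NULL,
                                 distinct = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k >= 1L, count >= 1L, length(tree$tip.label) >= 4L)
  src_id <- topology_id(tree)
  out <- vector("list", count)
  seen <- character(0)
  for (i in seq_len(count)) {
    ok <- FALSE
    for (try in 1:500) {
      tr <- tree
      prev <- src_id
      for (mv in seq_len(k)) {
        repeat {
          cand <- spr_random_move(tr)
          if (topology_id(cand) != prev) break
        }
        tr <- cand
        prev <- topology_id(tr)
      }
      id <- topology_id(tr)
      if (id == src_id) next
      if (distinct && id %in% seen) next
      out[[i]] <- tr; seen <- c(seen, id); ok <- TRUE
      break
    }
    if (!ok) stop("could not generate ", count,
                  " distinct SPR neighbors (neighborhood exhausted?)")
  }
  structure(out, class = "multiPhylo")
}

# --- four-taxon structured coalescent with one introgression pulse ----------

#' Specification of the introgression gene-tree simulation
#'
#' A pectinate 4-taxon species tree (((t1,t2),t3),t4) with divergence times
#' in coalescent units and a single introgression pulse from lineage t2's
#' population into lineage t4: at `mig_time`, the sampled t4 lineage moves
#' into population 2 with probability `rate`. The default divergence times
#' give substantial incomplete lineage sorting (internal branches of 0.5 and
#' 1 coalescent units); with no introgression the probability of each minor
#' quartet topology is exactly (1/3) exp(-0.5).
#'
#' @param rate introgression rate r in `[0, 1]`.
#' @param genes number of gene trees.
#' @param gene_length sites simulated per gene by
#'   [rescale_and_simulate_genes].
#' @param div_times divergence times (t12, t123, t1234) in coalescent units.
#' @param mig_time time of the introgression pulse (must precede t12).
#' @param scale branch-length rescale factor from coalescent units to
#'   substitutions/site.
#' @return an object of class `introgression_spec`.
#' @export
introgression_spec <- function(rate, genes = 1500L, gene_length = 1000L,
                               div_times = c(1.0, 1.5, 2.5), mig_time = 0.75,
                               scale = 0.002) {
  stopifnot(rate >= 0, rate <= 1, genes >= 1, gene_length >= 1,
            length(div_times) == 3L, all(diff(div_times) > 0),
            mig_time > 0, mig_time < div_times[1L])
  structure(list(rate = rate, genes = as.integer(genes),
                 gene_length = as.integer(gene_length),
                 div_times = as.numeric(div_times), mig_time = mig_time,
                 scale = scale),
            class = "introgression_spec")
}

# coalesce lineages within one population over [t0, t1); Inf t1 runs to one
# lineage.  lins: list of nodes (id, height); returns updated list + events.
.coalesce_interval <- function(lins, t0, t1, nodes, nextid) {
  t <- t0
  while (length(lins) >= 2L) {
    k <- length(lins)
    dt <- stats::rexp(1L, rate = k * (k - 1) / 2)
    if (t + dt >= t1) break
    t <- t + dt
    pair <- sample.int(k, 2L)
    id <- nextid
    nodes[[id]] <- list(children = c(lins[[pair[1L]]], lins[[pair[2L]]]),
                        height = t)
    lins <- c(lins[-pair], id)
    nextid <- nextid + 1L
  }
  list(lins = lins, nodes = nodes, nextid = nextid)
}

#' Sample gene trees under the introgression model
#'
#' @param spec an [introgression_spec].
#' @param seed optional RNG seed.
#' @return list of rooted `phylo` gene trees with coalescent-unit branch
#'   lengths; attribute `topology` gives each gene's unrooted quartet class
#'   (`"TE1"` = species-tree split t1t2|t3t4, `"TE2"` = introgression split
#'   t2t4|t1t3, `"TE3"` = t1t4|t2t3).
#' @export
sample_introgression_gene_trees <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "introgression_spec"))
  tt <- spec$div_times; tm <- spec$mig_time
  te_ids <- c(TE1 = topology_id(ape::read.tree(text = "((t1,t2),(t3,t4));")),
              TE2 = topology_id(ape::read.tree(text = "((t2,t4),(t1,t3));")),
              TE3 = topology_id(ape::read.tree(text = "((t1,t4),(t2,t3));")))
  trees <- vector("list", spec$genes)
  topo <- character(spec$genes)
  for (gn in seq_len(spec$genes)) {
    nodes <- vector("list", 7L)
    for (i in 1:4) nodes[[i]] <- list(children = NULL, height = 0)
    nextid <- 5L
    migrated <- stats::runif(1L) < spec$rate
    pop2 <- if (migrated) list(2L, 4L) else list(2L)        # lineage ids
    # [mig_time, t12): only pop2 can hold 2 lineages
    st <- .coalesce_interval(pop2, tm, tt[1L], nodes, nextid)
    pop2 <- st$lins; nodes <- st$nodes; nextid <- st$nextid
    # [t12, t123): pops 1+2 merged
    pop12 <- c(list(1L), pop2)
    st <- .coalesce_interval(pop12, tt[1L], tt[2L], nodes, nextid)
    pop12 <- st$lins; nodes <- st$nodes; nextid <- st$nextid
    # [t123, t1234): pop3 joins
    pop123 <- c(pop12, list(3L))
    st <- .coalesce_interval(pop123, tt[2L], tt[3L], nodes, nextid)
    pop123 <- st$lins; nodes <- st$nodes; nextid <- st$nextid
    # root population: remaining t4 lineage (if not migrated) joins
    root_pop <- if (migrated) pop123 else c(pop123, list(4L))
    st <- .coalesce_interval(root_pop, tt[3L], Inf, nodes, nextid)
    nodes <- st$nodes
    root <- st$lins[[1L]]
    nwk <- local({
      rec <- function(id, parent_h) {
        nd <- nodes[[id]]
        blen <- parent_h - nd$height
        if (is.null(nd$children))
          return(paste0("t", id, ":", format(blen, digits = 12)))
        paste0("(", paste(vapply(unlist(nd$children), rec, "",
                                 parent_h = nd$height), collapse = ","),
               ")", if (is.finite(blen)) paste0(":", format(blen, digits = 12)))
      }
      paste0(rec(root, Inf), ";")
    })
    tr <- ape::read.tree(text = nwk)
    trees[[gn]] <- tr
    topo[gn] <- names(te_ids)[match(topology_id(tr), te_ids)]
  }
  attr(trees, "topology") <- topo
  trees
}

#' Rescale gene trees and simulate a concatenated alignment
#'
#' Multiplies every branch length by `factor` (coalescent units to
#' substitutions/site), simulates each gene independently under the given
#' model, and concatenates the per-gene alignments.
#'
#' @param gene_trees list of `phylo` gene trees.
#' @param cm a [class_model] supplying the substitution model.
#' @param factor branch-length rescale factor.
#' @param gene_length sites per gene.
#' @param seed optional RNG seed.
#' @return list with `alignment` and `labels` (per-site gene index; the
#'   per-site quartet topology is in attribute `topology` when the input
#'   carries one).
#' @export
rescale_and_simulate_genes <- function(gene_trees, cm, factor = 0.002,
                                       gene_length = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ng <- length(gene_trees)
  alns <- vector("list", ng)
  first <- NULL
  for (gn in seq_len(ng)) {
    tr <- gene_trees[[gn]]
    tr$edge.length <- tr$edge.length * factor
    a <- simulate_alignment(tr, cm, gene_length)
    if (is.null(first)) first <- sort(a$labels)
    alns[[gn]] <- a$states[match(first, a$labels), , drop = FALSE]
  }
  states <- do.call(cbind, alns)
  rownames(states) <- first
  labels <- rep(seq_len(ng), each = gene_length)
  out <- list(alignment = structure(list(labels = first, states = states,
                                         nsites = ncol(states)),
                                    class = "mast_alignment"),
              labels = labels)
  if (!is.null(attr(gene_trees, "topology")))
    attr(out, "topology") <- rep(attr(gene_trees, "topology"),
                                 each = gene_length)
  out
}

#' Root-mean-squared error between weight vectors
#'
#' @param estimated,truth equal-length weight vectors with matched class
#'   order.
#' @return scalar RMSE.
#' @export
weight_rmse <- function(estimated, truth) {
  if (length(estimated) != length(truth))
    stop("weight vectors differ in length")
  sqrt(mean((estimated - truth)^2))
}
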