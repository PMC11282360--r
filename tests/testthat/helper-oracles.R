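# Independent oracles and fixture builders used across the suite.  Nothing
# here calls the pruning kernel: the enumeration oracle multiplies transition
# probabilities over explicit internal-state assignments.

# random unrooted topology with standard tip labels
rand_topo <- function(ntaxa) {
  ape::rtopology(ntaxa, rooted = FALSE, tip.label = paste0("t", seq_len(ntaxa)))
}

rand_class_model <- function(ntaxa, ncat = 4L) {
  p <- draw_model_params()
  class_model(draw_branch_lengths(rand_topo(ntaxa)),
              p$gtr, p$freqs, discretize_gamma(p$alpha, ncat))
}

# alignment from explicit sequence strings
aln_from_strings <- function(...) {
  mast_alignment(unlist(list(...)))
}

# Exhaustive-enumeration site log-likelihoods: sum over all joint internal
# node states of products of transition probabilities, averaged over gamma
# categories.  Only feasible for small trees.
brute_force_site_logliks <- function(tree, cm, paln) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  rm <- build_rate_matrix(cm$gtr, cm$freqs)
  rates <- cm$rhas$rates
  nt <- length(tr$tip.label)
  ntot <- nt + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1L]
  internals <- (nt + 1L):ntot
  st <- paln$states[match(tr$tip.label, paln$labels), , drop = FALSE]
  npat <- ncol(st)
  out <- numeric(npat)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  for (pat in seq_len(npat)) {
    tot <- 0
    for (k in seq_along(rates)) {
      P <- lapply(tr$edge.length,
                  function(t) transition_probabilities(rm, t, rates[k]))
      s <- 0
      for (g in seq_len(nrow(grid))) {
        asgn <- integer(ntot)
        asgn[internals] <- grid[g, ]
        term <- rm$pi[asgn[root]]
        for (e in seq_len(nrow(tr$edge))) {
          u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
          if (v <= nt) {
            bits <- which(bitwAnd(st[v, pat], c(1L, 2L, 4L, 8L)) > 0L)
            term <- term * sum(P[[e]][asgn[u], bits])
          } else {
            term <- term * P[[e]][asgn[u], asgn[v]]
          }
        }
        s <- s + term
      }
      tot <- tot + s / length(rates)
    }
    out[pat] <- log(tot)
  }
  out
}

# phangorn phyDat from a pattern alignment (oracle-side data conversion)
as_phyDat <- function(paln) {
  ch <- matrix(c("a", "c", "g", "t")[log2(paln$states) + 1],
               nrow = nrow(paln$states),
               dimnames = list(paln$labels, NULL))
  phangorn::phyDat(ch[, paln$site_map])
}

# Brute-force Fitch score of one site column: minimize state changes over all
# internal-node labelings.
brute_force_fitch <- function(tree, states_bitmask) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  nt <- length(tr$tip.label)
  ntot <- nt + tr$Nnode
  internals <- (nt + 1L):ntot
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  st <- states_bitmask[match(tr$tip.label, names(states_bitmask))]
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asgn <- integer(ntot)
    asgn[internals] <- grid[g, ]
    changes <- 0
    for (e in seq_len(nrow(tr$edge))) {
      u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
      su <- 2L^(asgn[u] - 1L)
      if (v <= nt) {
        if (bitwAnd(st[v], su) == 0L) changes <- changes + 1
      } else {
        if (asgn[v] != asgn[u]) changes <- changes + 1
      }
    }
    best <- min(best, changes)
  }
  best
}
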