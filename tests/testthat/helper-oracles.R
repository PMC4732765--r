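# Independent oracles: brute-force enumeration of tree likelihoods and
# marginal posteriors over all internal-state assignments, used to check the
# pruning implementations on small trees.

# Enumerate the likelihood of one alignment column by summing over every
# assignment of states to internal nodes. Works for any ctmc_model and any
# rooted/unrooted ape tree small enough to enumerate.
brute_force_column <- function(tree, column, model) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nst <- length(model$states)
  obs <- match(column[tree$tip.label], model$states)
  internal <- (ntip + 1L):nnode
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_prob(model, tree$edge.length[e])
  })
  root <- ntip + 1L
  grid <- do.call(expand.grid, rep(list(seq_len(nst)), length(internal)))
  total <- 0
  joint <- matrix(0, nrow(grid), length(internal))
  probs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(v) {
      if (v <= ntip) obs[v] else grid[g, match(v, internal)]
    }
    p <- model$freqs[assign_state(root)]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_state(tree$edge[e, 1])
      b <- assign_state(tree$edge[e, 2])
      if (is.na(b)) next  # missing leaf: marginalized, handled below
      p <- p * Pm[[e]][a, b]
    }
    probs[g] <- p
  }
  list(likelihood = sum(probs), grid = grid, probs = probs,
       internal = internal)
}

# Marginal posterior of each internal node's state from the enumeration.
brute_force_posteriors <- function(tree, column, model) {
  bf <- brute_force_column(tree, column, model)
  nst <- length(model$states)
  lapply(seq_along(bf$internal), function(k) {
    post <- vapply(seq_len(nst), function(s) {
      sum(bf$probs[bf$grid[, k] == s])
    }, numeric(1))
    post / sum(post)
  })
}

# one-column aa_alignment from a named character vector of residues
column_alignment <- function(residues) {
  aa_alignment(vapply(residues, identity, character(1)))
}

# mean pairwise percent identity of a set of equal-length sequences
mean_pairwise_identity <- function(seqs) {
  prs <- utils::combn(length(seqs), 2)
  mean(vapply(seq_len(ncol(prs)), function(k) {
    percent_identity(seqs[[prs[1, k]]], seqs[[prs[2, k]]])
  }, numeric(1)))
}

# fixed 4-taxon test tree with named internal nodes
four_taxon_tree <- function(bl = c(0.2, 0.3, 0.15, 0.1, 0.25, 0.05)) {
  ape::read.tree(text = sprintf(
    "((t1:%g,t2:%g)N2:%g,(t3:%g,t4:%g)N3:%g)N1;",
    bl[1], bl[2], bl[3], bl[4], bl[5], bl[6]))
}
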