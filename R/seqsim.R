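# Synthetic-data generators: families evolved along known trees (with true
# ancestral sequences kept as oracle), synthetic genomes with configurable
# hisA/hisF/hisH neighborhoods, and identity-structured homolog sets.

#' Sample a Yule (pure-birth) tree
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Speciation rate; branch lengths are in expected
#'   substitutions per site (1 / birth_rate time scale).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return A rooted binary `ape::phylo` with `n_taxa` leaves, positive branch
#'   lengths, tip labels `t1..tn` and node labels `N1..N(n-1)`.
#' @export
sample_yule_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 2) stop_invalid("`n_taxa` must be >= 2")
  check_scalar_number(birth_rate, "birth_rate", positive = TRUE)
  tree <- with_seed(seed, ape::rphylo(as.integer(n_taxa), birth = birth_rate,
                                      death = 0, fossils = FALSE))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree$node.label <- paste0("N", seq_len(tree$Nnode))
  # guard against zero-length branches from coincident event times
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  tree
}

node_ids <- function(tree) {
  c(tree$tip.label,
    if (!is.null(tree$node.label)) tree$node.label
    else paste0("N", seq_len(tree$Nnode)))
}

#' Evolve a protein family along a tree
#'
#' Simulates amino-acid sequences down a rooted tree under a reversible
#' empirical substitution model with optional indels. The root sequence is
#' drawn from the model's equilibrium frequencies; each branch applies exact
#' CTMC endpoint substitutions via `P(t)` and a Poisson number of indel
#' events (insertion:deletion 1:1, geometric lengths, uniform placement).
#' True (ungapped) sequences of every internal node are retained, and the
#' implied true alignment — including the columns created by insertions — is
#' returned for the leaves and the ancestors.
#'
#' @param tree Rooted binary `phylo` with branch lengths >= 0.
#' @param root_length Root sequence length (>= 1).
#' @param model A `ctmc_model` from [aa_model()].
#' @param indel_rate Expected indel events per site per unit branch length.
#' @param indel_ext Geometric length parameter p; indel length ~ 1 + Geom(p).
#' @param seed Integer seed.
#' @return A `simulated_family`: list with `tree`, `alignment` (leaves,
#'   `aa_alignment`), `ancestor_alignment` (internal nodes, gapped, same
#'   columns), `true_ancestors` (named ungapped sequences), `seed`.
#' @export
evolve_alignment <- function(tree, root_length, model = aa_model("JTT"),
                             indel_rate = 0, indel_ext = 0.3, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (root_length < 1) stop_invalid("`root_length` must be >= 1")
  if (any(tree$edge.length < 0)) stop_invalid("negative branch length")
  check_scalar_number(indel_rate, "indel_rate", nonneg = TRUE)
  ntip <- length(tree$tip.label)
  ids <- node_ids(tree)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  states <- model$states
  nst <- length(states)

  sim <- with_seed(seed, {
    seqs <- vector("list", nnode)  # each: list(key = numeric, state = integer)
    root_states <- sample.int(nst, root_length, replace = TRUE,
                              prob = model$freqs)
    seqs[[root]] <- list(key = as.numeric(seq_len(root_length)),
                         state = root_states)
    # preorder over edges
    ord <- order(tree$edge[, 1])
    edges <- tree$edge[ord, , drop = FALSE]
    lens <- tree$edge.length[ord]
    # process edges so that parents come before children
    done <- rep(FALSE, nnode); done[root] <- TRUE
    pending <- seq_len(nrow(edges))
    while (length(pending)) {
      ready <- pending[done[edges[pending, 1]]]
      for (e in ready) {
        par <- edges[e, 1]; child <- edges[e, 2]; t <- lens[e]
        s <- seqs[[par]]
        key <- s$key; st <- s$state
        if (t > 0 && length(st)) {
          P <- transition_prob(model, t)
          st <- vapply(st, function(a) {
            sample.int(nst, 1L, prob = P[a, ])
          }, integer(1))
        }
        if (indel_rate > 0 && length(st)) {
          n_ev <- rpois(1, indel_rate * t * length(st))
          for (ev in seq_len(n_ev)) {
            L <- length(st)
            g <- rgeom(1, indel_ext) + 1L
            if (runif(1) < 0.5 && L > 0) {          # deletion
              start <- sample.int(L, 1L)
              idx <- start:min(L, start + g - 1L)
              key <- key[-idx]; st <- st[-idx]
            } else {                                 # insertion
              pos <- sample.int(L + 1L, 1L) - 1L     # after site `pos`
              kl <- if (pos == 0L) (if (L) key[1] - 1 else 0) else key[pos]
              kr <- if (pos == L) kl + 1 else key[pos + 1L]
              newk <- kl + (kr - kl) * seq_len(g) / (g + 1)
              news <- sample.int(nst, g, replace = TRUE, prob = model$freqs)
              key <- append(key, newk, after = pos)
              st <- append(st, news, after = pos)
            }
          }
        }
        seqs[[child]] <- list(key = key, state = st)
        done[child] <- TRUE
      }
      pending <- setdiff(pending, ready)
    }
    seqs
  })

  all_keys <- sort(unique(unlist(lapply(sim, `[[`, "key"))))
  to_row <- function(s) {
    row <- rep("-", length(all_keys))
    row[match(s$key, all_keys)] <- states[s$state]
    row
  }
  mat <- do.call(rbind, lapply(sim, to_row))
  rownames(mat) <- ids
  leaf_aln <- aa_alignment(mat[seq_len(ntip), , drop = FALSE])
  anc_aln <- aa_alignment(mat[(ntip + 1L):nnode, , drop = FALSE])
  true_anc <- vapply(sim[(ntip + 1L):nnode], function(s) {
    paste(states[s$state], collapse = "")
  }, character(1))
  names(true_anc) <- ids[(ntip + 1L):nnode]
  structure(list(tree = tree, alignment = leaf_aln,
                 ancestor_alignment = anc_aln,
                 true_ancestors = true_anc, seed = seed),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("<simulated_family> %d leaves, %d columns, %d true ancestors\n",
              nrow(x$alignment$mat), ncol(x$alignment$mat),
              length(x$true_ancestors)))
  invisible(x)
}

#' Expected fraction of differing sites across a branch
#'
#' `sum_i pi_i (1 - P_ii(t))`: the probability that the states at the two
#' ends of a branch of length `t` differ at a site, under the model at
#' stationarity. Useful as the exact reference for divergence checks on
#' simulated data.
#'
#' @param model A `ctmc_model`.
#' @param t Branch length.
#' @return Probability in `[0, 1]`.
#' @export
expected_diff_fraction <- function(model, t) {
  P <- transition_prob(model, t)
  sum(model$freqs * (1 - diag(P)))
}

#' Generate a homolog family with block identity structure
#'
#' Creates blocks of sequences sharing a common random ancestor; within a
#' block each sequence mutates each site independently with a rate chosen so
#' the expected pairwise identity matches the target. Sequences from
#' different blocks are unrelated (background ~5% identity).
#'
#' @param n_seqs Total number of sequences.
#' @param length Sequence length.
#' @param identity_blocks Data frame (or list of pairs) with columns
#'   `size` and `identity` (fraction in (0.06, 1]); sizes must sum to
#'   `n_seqs`.
#' @param seed Integer seed.
#' @return Named character vector (`b<block>_s<i>`), with attribute
#'   `"block"` giving each sequence's block index.
#' @export
make_family_with_identity <- function(n_seqs, length, identity_blocks,
                                      seed = 1L) {
  blocks <- if (is.data.frame(identity_blocks)) identity_blocks
            else tibble(size = vapply(identity_blocks, `[[`, numeric(1), 1),
                        identity = vapply(identity_blocks, `[[`, numeric(1), 2))
  if (sum(blocks$size) != n_seqs) {
    stop_invalid("block sizes must sum to `n_seqs`")
  }
  background <- 1 / 19  # expected identity of unrelated uniform sequences
  if (any(blocks$identity <= background + 0.01)) {
    stop_invalid("identity target below background expectation (~5%%)")
  }
  # expected pairwise identity when each of two copies mutates a site with
  # prob m (to a uniform different residue): (1-m)^2 + m^2/19
  m_for <- function(target) {
    if (target >= 1) return(0)
    stats::uniroot(function(m) (1 - m)^2 + m^2 / 19 - target,
                   c(0, 0.95))$root
  }
  st <- aa_states()
  with_seed(seed, {
    out <- character(0)
    block_of <- integer(0)
    for (b in seq_len(nrow(blocks))) {
      anc <- sample(st, length, replace = TRUE)
      m <- m_for(blocks$identity[b])
      for (i in seq_len(blocks$size[b])) {
        s <- anc
        hit <- runif(length) < m
        if (any(hit)) {
          s[hit] <- vapply(s[hit], function(a) sample(setdiff(st, a), 1L),
                           character(1))
        }
        out <- c(out, paste(s, collapse = ""))
        block_of <- c(block_of, b)
      }
    }
    names(out) <- paste0("b", block_of, "_s",
                         stats::ave(block_of, block_of, FUN = seq_along))
    attr(out, "block") <- block_of
    out
  })
}

#' Generate synthetic genomes with controlled marker-gene neighborhoods
#'
#' Builds one gene table per species. In `round(neighbor_fraction * n)`
#' genomes the three marker genes (hisA/hisF/hisH) occupy consecutive gene
#' indices in a random internal order on the same strand; in the remaining
#' genomes they are either scattered with at least two intervening decoy
#' genes or one marker is dropped.
#'
#' @param families Named list mapping gene name to a named character vector
#'   of per-species protein sequences; must contain `hisA`, `hisF`, `hisH`,
#'   all with identical species names.
#' @param neighbor_fraction Fraction of species with adjacent markers.
#' @param decoy_genes Number of decoy genes per genome.
#' @param seed Integer seed.
#' @return A tibble gene table with columns `species_id`, `contig`,
#'   `gene_index`, `gene`, `strand`, `protein`.
#' @export
make_genomes <- function(families, neighbor_fraction, decoy_genes = 10L,
                         seed = 1L) {
  markers <- c("hisA", "hisF", "hisH")
  if (!all(markers %in% names(families))) {
    stop_invalid("`families` must contain hisA, hisF and hisH")
  }
  if (neighbor_fraction < 0 || neighbor_fraction > 1) {
    stop_invalid("`neighbor_fraction` must be in [0, 1]")
  }
  species <- names(families$hisA)
  n <- length(species)
  n_neighbor <- round(neighbor_fraction * n)
  st <- aa_states()
  with_seed(seed, {
    neighbor_species <- sample(species, n_neighbor)
    rows <- purrr::map_dfr(species, function(sp) {
      is_nb <- sp %in% neighbor_species
      decoys <- tibble(
        gene = paste0("decoy", seq_len(decoy_genes)),
        strand = sample(c("+", "-"), decoy_genes, replace = TRUE),
        protein = vapply(seq_len(decoy_genes), function(i) {
          paste(sample(st, 150, replace = TRUE), collapse = "")
        }, character(1)))
      marker_rows <- tibble(gene = sample(markers), strand = "+")
      marker_rows$protein <- vapply(marker_rows$gene,
                                    function(g) families[[g]][[sp]],
                                    character(1))
      if (is_nb) {
        pos <- sample.int(decoy_genes + 1L, 1L) - 1L  # insert after pos decoys
        genes <- dplyr::bind_rows(decoys[seq_len(pos), ], marker_rows,
                                  decoys[seq(pos + 1, length.out = decoy_genes - pos), ])
      } else if (runif(1) < 0.5 || decoy_genes < 7L) {
        # drop one marker, scatter the remaining two anywhere
        kept <- marker_rows[-sample.int(3L, 1L), ]
        genes <- decoys
        for (k in seq_len(nrow(kept))) {
          at <- sample.int(nrow(genes) + 1L, 1L) - 1L
          genes <- dplyr::bind_rows(genes[seq_len(at), ], kept[k, ],
                                    genes[seq(at + 1, length.out = nrow(genes) - at), ])
        }
      } else {
        # scatter all three with >= 2 intervening decoys between consecutive
        n_total <- decoy_genes + 3L
        pos <- c(1L, 4L, 7L)  # marker positions, two decoys between each
        genes <- tibble(gene = character(n_total), strand = character(n_total),
                        protein = character(n_total))
        ordm <- sample(3L)
        genes[pos, ] <- marker_rows[ordm, ]
        genes[setdiff(seq_len(n_total), pos), ] <- decoys
      }
      dplyr::mutate(genes, species_id = sp, contig = "c1",
                    gene_index = dplyr::row_number(), .before = 1)
    })
    dplyr::select(rows, "species_id", "contig", "gene_index", "gene",
                  "strand", "protein")
  })
}
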