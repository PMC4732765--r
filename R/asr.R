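# Marginal ancestral sequence reconstruction (residues + indel states).

#' Marginal ancestral residue posteriors
#'
#' For every node of a rooted tree, computes the per-column marginal
#' posterior distribution over residues given the leaf alignment:
#' `P(state | data)` proportional to the equilibrium-weighted product of the
#' upward (subtree) partial likelihoods below the node and the downward
#' partials from the rest of the tree. With a gamma model, categories are
#' weighted by their per-column posterior probability.
#'
#' @param tree Rooted binary `phylo`; leaf set must equal the alignment rows.
#' @param aln An `aa_alignment` of the leaves.
#' @param model A `ctmc_model` (default JTT).
#' @return Named list (one entry per node id, leaves included) of
#'   `n_states x n_columns` posterior matrices, columns summing to 1.
#' @export
marginal_posteriors <- function(tree, aln, model = aa_model("JTT")) {
  if (!ape::is.rooted(tree)) {
    stop_invalid("ancestral reconstruction requires a rooted tree")
  }
  .marginal_engine(tree, aln, model)
}

#' Marginal indel (presence/absence) reconstruction
#'
#' Recodes each alignment column as binary residue presence and runs the
#' same marginal machinery under a reversible two-state CTMC with equal
#' equilibrium frequencies and rate `gain_loss_rate`.
#'
#' @param aln An `aa_alignment`.
#' @param tree Rooted binary `phylo`.
#' @param gain_loss_rate Gain/loss rate on the tree's branch-length scale.
#' @return Named list (per node id) of numeric vectors: per-column posterior
#'   probability that a residue is present.
#' @export
reconstruct_indels <- function(aln, tree, gain_loss_rate = 1) {
  if (!ape::is.rooted(tree)) {
    stop_invalid("indel reconstruction requires a rooted tree")
  }
  pm <- presence_model(gain_loss_rate)
  bin <- ifelse(aln$mat == "-", "0", "1")
  rownames(bin) <- rownames(aln$mat)
  baln <- aa_alignment(bin, column_map = aln$column_map)
  post <- .marginal_engine(tree, baln, pm)
  lapply(post, function(m) unname(m["1", ]))
}

#' Full ancestral reconstruction (residues + indels)
#'
#' Combines marginal residue posteriors with presence posteriors into one
#' most-likely gapped sequence per node: a column emits the argmax residue
#' when its presence posterior is at least 0.5 (presence-favoring at the
#' tie), otherwise a gap. Argmax ties are broken alphabetically.
#'
#' @inheritParams marginal_posteriors
#' @param gain_loss_rate Rate of the indel gain/loss process.
#' @return An `asr_reconstruction`: list with `tree`, `residue_posteriors`,
#'   `presence_posteriors`, and a tibble `nodes` (node, ml_sequence,
#'   mean_posterior).
#' @export
ancestral_reconstruction <- function(tree, aln, model = aa_model("JTT"),
                                     gain_loss_rate = 1) {
  res <- marginal_posteriors(tree, aln, model)
  pres <- reconstruct_indels(aln, tree, gain_loss_rate)
  any_gap <- any(aln$mat == "-")
  nodes <- purrr::map_dfr(names(res), function(id) {
    m <- res[[id]]
    p <- if (any_gap) pres[[id]] else rep(1, ncol(m))
    chars <- vapply(seq_len(ncol(m)), function(j) {
      if (p[j] < 0.5) return("-")
      col <- m[, j]
      top <- which(col >= max(col) - 1e-12)
      model$states[top[order(model$states[top])[1]]]
    }, character(1))
    emitted <- chars != "-"
    mp <- if (any(emitted)) {
      mean(vapply(which(emitted), function(j) m[chars[j], j], numeric(1)))
    } else NA_real_
    tibble(node = id, ml_sequence = paste(chars, collapse = ""),
           mean_posterior = mp)
  })
  structure(list(tree = tree, alignment = aln,
                 residue_posteriors = res, presence_posteriors = pres,
                 nodes = nodes),
            class = "asr_reconstruction")
}

#' @export
print.asr_reconstruction <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat(sprintf("<asr_reconstruction> %d nodes (%d internal), %d columns\n",
              nrow(x$nodes), x$tree$Nnode, ncol(x$alignment$mat)))
  invisible(x)
}

#' Tidy per-column ancestral posteriors
#' @param x An `asr_reconstruction`.
#' @param nodes Optional node ids to include (default: internal nodes).
#' @param ... Unused.
#' @return Tibble with columns node, column, residue, prob.
#' @export
#' @importFrom generics tidy
tidy.asr_reconstruction <- function(x, nodes = NULL, ...) {
  if (is.null(nodes)) nodes <- x$tree$node.label %||% setdiff(
    names(x$residue_posteriors), x$tree$tip.label)
  purrr::map_dfr(nodes, function(id) {
    m <- x$residue_posteriors[[id]]
    tibble(node = id,
           column = rep(seq_len(ncol(m)), each = nrow(m)),
           residue = rep(rownames(m), ncol(m)),
           prob = as.vector(m))
  })
}

#' Reconstruction at the ancestor of a clade
#'
#' Returns the reconstruction row for the most recent common ancestor of the
#' given leaves. The MRCA of a single leaf is defined as the leaf itself.
#'
#' @param recon An `asr_reconstruction`.
#' @param clade Character vector of leaf labels (non-empty).
#' @return One-row tibble (node, ml_sequence, mean_posterior).
#' @export
extract_ancestor <- function(recon, clade) {
  if (length(clade) == 0L) stop_invalid("`clade` must be non-empty")
  tree <- recon$tree
  missing <- setdiff(clade, tree$tip.label)
  if (length(missing)) {
    stop_invalid("leaves not in tree: %s", paste(missing, collapse = ", "))
  }
  id <- if (length(clade) == 1L) {
    clade
  } else {
    node <- ape::getMRCA(tree, clade)
    node_ids(tree)[node]
  }
  dplyr::filter(recon$nodes, .data$node == id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
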