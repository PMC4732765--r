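# Felsenstein pruning over arbitrary reversible CTMC models, with per-column
# rescaling, site-pattern compression, discrete-gamma mixing, and the
# outside (down) pass needed for marginal ancestral reconstruction.

# alignment -> integer matrix (rows = taxa, cols = columns), NA = missing
encode_alignment <- function(aln, model) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- aln$mat
  enc <- match(m, model$states)
  enc[m %in% .missing_chars] <- NA_integer_
  bad <- !is.na(m) & is.na(enc) & !(m %in% .missing_chars)
  if (any(bad)) enc[bad] <- NA_integer_  # unknown characters -> missing
  dim(enc) <- dim(m)
  rownames(enc) <- rownames(m)
  enc
}

# unique columns + weights
site_patterns <- function(enc) {
  keys <- apply(enc, 2, paste, collapse = "\r")
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  list(patterns = enc[, first, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_len(sum(first))))),
       col_to_pattern = idx)
}

check_tree_aln <- function(tree, aln) {
  if (is.null(tree$edge.length)) stop_invalid("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_invalid("negative branch length")
  labs <- rownames(aln$mat)
  if (!setequal(tree$tip.label, labs)) {
    stop_invalid("tree leaf set does not match alignment row labels")
  }
}

# Upward (pruning) pass for one rate category.
# Returns partials for every node (nst x npat each) and per-node log scale
# vectors (npat), plus per-pattern log-likelihood at the root.
.prune_up <- function(tree, pat, model, rate = 1) {
  nst <- length(model$states)
  npat <- ncol(pat$patterns)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", nnode)
  scalelog <- matrix(0, nnode, npat)
  tipidx <- match(tree$tip.label, rownames(pat$patterns))
  for (i in seq_len(ntip)) {
    L <- matrix(0, nst, npat)
    s <- pat$patterns[tipidx[i], ]
    miss <- is.na(s)
    L[, miss] <- 1
    if (any(!miss)) L[cbind(s[!miss], which(!miss))] <- 1
    partial[[i]] <- L
  }
  Pmats <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    Pmats[[e]] <- transition_prob(model, tr$edge.length[e], rate)
  }
  parents <- unique(tr$edge[, 1])  # postorder: children before parents
  for (p in parents) {
    es <- which(tr$edge[, 1] == p)
    L <- matrix(1, nst, npat)
    slog <- rep(0, npat)
    for (e in es) {
      ch <- tr$edge[e, 2]
      L <- L * (Pmats[[e]] %*% partial[[ch]])
      slog <- slog + scalelog[ch, ]
    }
    mx <- apply(L, 2, max)
    mx[mx <= 0] <- 1
    partial[[p]] <- sweep(L, 2, mx, "/")
    scalelog[p, ] <- slog + log(mx)
  }
  root <- ntip + 1L
  site_loglik <- log(colSums(model$freqs * partial[[root]])) + scalelog[root, ]
  list(partial = partial, scalelog = scalelog, site_loglik = site_loglik,
       tr = tr, Pmats = Pmats, root = root)
}

#' Tree log-likelihood by the pruning algorithm
#'
#' Computes the log-likelihood of an alignment on a tree under a reversible
#' substitution model, with per-column rescaling against underflow,
#' site-pattern compression, gaps/ambiguities treated as missing data, and
#' equal-weight discrete-gamma rate mixing when the model carries a shape
#' parameter.
#'
#' @param tree `phylo` whose leaf set equals the alignment row labels;
#'   branch lengths >= 0 in expected substitutions per site.
#' @param aln An `aa_alignment`.
#' @param model A `ctmc_model`.
#' @return The log-likelihood (a single number).
#' @export
tree_log_likelihood <- function(tree, aln, model = aa_model("JTT")) {
  check_tree_aln(tree, aln)
  pat <- site_patterns(encode_alignment(aln, model))
  rates <- model_rates(model)
  if (length(rates) == 1L) {
    ll <- .prune_up(tree, pat, model, rates)$site_loglik
  } else {
    per_cat <- vapply(rates, function(r) {
      .prune_up(tree, pat, model, r)$site_loglik
    }, numeric(length(pat$weights)))
    mx <- apply(per_cat, 1, max)
    ll <- mx + log(rowMeans(exp(per_cat - mx)))
  }
  sum(pat$weights * ll)
}

# Outside/downward pass for one category: returns per-node "above" partials
# A (nst x npat), with the root prior (equilibrium frequencies) included.
# Only relative per-column values are meaningful (columns are rescaled).
.prune_down <- function(up, model) {
  tr <- up$tr
  nst <- length(model$states)
  npat <- ncol(up$partial[[1]])
  nnode <- length(up$partial)
  A <- vector("list", nnode)
  A[[up$root]] <- matrix(model$freqs, nst, npat)
  # preorder = reverse postorder over edges
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    contrib <- A[[p]]
    sibs <- setdiff(which(tr$edge[, 1] == p), e)
    for (s in sibs) {
      contrib <- contrib * (up$Pmats[[s]] %*% up$partial[[tr$edge[s, 2]]])
    }
    Ac <- crossprod(up$Pmats[[e]], contrib)  # t(P) %*% contrib
    mx <- apply(Ac, 2, max)
    mx[mx <= 0] <- 1
    A[[ch]] <- sweep(Ac, 2, mx, "/")
  }
  A
}

# Marginal posteriors for every node under one model (handles gamma mixing
# by weighting categories with their per-column posterior probability).
.marginal_engine <- function(tree, aln, model) {
  check_tree_aln(tree, aln)
  pat <- site_patterns(encode_alignment(aln, model))
  rates <- model_rates(model)
  nst <- length(model$states)
  npat <- length(pat$weights)
  nnode <- length(tree$tip.label) + tree$Nnode
  post <- replicate(nnode, matrix(0, nst, npat), simplify = FALSE)
  cat_ll <- matrix(0, length(rates), npat)
  per_cat <- vector("list", length(rates))
  for (k in seq_along(rates)) {
    up <- .prune_up(tree, pat, model, rates[k])
    A <- .prune_down(up, model)
    cat_ll[k, ] <- up$site_loglik
    per_cat[[k]] <- lapply(seq_len(nnode), function(v) {
      m <- A[[v]] * up$partial[[v]]
      sweep(m, 2, pmax(colSums(m), .Machine$double.xmin), "/")
    })
  }
  # category posterior weights per pattern
  mx <- apply(cat_ll, 2, max)
  w <- exp(sweep(cat_ll, 2, mx, "-"))
  w <- sweep(w, 2, colSums(w), "/")
  for (k in seq_along(rates)) {
    for (v in seq_len(nnode)) {
      post[[v]] <- post[[v]] + sweep(per_cat[[k]][[v]], 2, w[k, ], "*")
    }
  }
  # expand patterns back to columns
  ids <- node_ids(tree)
  out <- lapply(seq_len(nnode), function(v) {
    m <- post[[v]][, pat$col_to_pattern, drop = FALSE]
    rownames(m) <- model$states
    m
  })
  names(out) <- ids
  out
}
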