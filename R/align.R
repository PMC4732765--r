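# Progressive profile-profile alignment: k-mer guide tree + affine-gap
# Needleman-Wunsch on profiles. Gap cost convention matches
# Biostrings::pairwiseAlignment: a gap of length L costs |open| + L * |ext|.

#' BLOSUM62 scoring matrix over the 20 amino acids
#' @return 20 x 20 integer score matrix in `aa_states()` order.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[aa_states(), aa_states()]
}

# k-mer count vectors -> cosine distance matrix
kmer_cosine_distances <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    kmers <- substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    table(kmers)
  })
  all_kmers <- unique(unlist(lapply(counts, names)))
  V <- vapply(counts, function(ct) {
    v <- numeric(length(all_kmers))
    names(v) <- all_kmers
    v[names(ct)] <- as.numeric(ct)
    v
  }, numeric(length(all_kmers)))
  nrm <- sqrt(colSums(V^2))
  nrm[nrm == 0] <- 1
  Vn <- sweep(V, 2, nrm, "/")
  D <- 1 - crossprod(Vn)
  D[D < 0] <- 0
  diag(D) <- 0
  rownames(D) <- colnames(D) <- names(seqs)
  D
}

# residue-proportion profile (20 x ncols); gaps contribute no residue mass
profile_of <- function(mat) {
  st <- aa_states()
  P <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- tabulate(match(mat[, j], st), nbins = 20L)
    tab / nrow(mat)
  }, numeric(20L))
  matrix(P, nrow = 20L)
}

# affine-gap global alignment of two profiles; returns the merged matrix
align_profiles <- function(matA, matB, B, gap_open, gap_extend) {
  FA <- profile_of(matA)
  FB <- profile_of(matB)
  S <- t(FA) %*% B %*% FB
  na <- ncol(matA); nb <- ncol(matB)
  NEG <- -1e18
  M <- matrix(NEG, na + 1, nb + 1)
  X <- matrix(NEG, na + 1, nb + 1)  # column of A against gap
  Y <- matrix(NEG, na + 1, nb + 1)  # column of B against gap
  pM <- matrix(0L, na + 1, nb + 1)
  pX <- matrix(0L, na + 1, nb + 1)
  pY <- matrix(0L, na + 1, nb + 1)
  M[1, 1] <- 0
  for (i in seq_len(na)) {
    X[i + 1, 1] <- gap_open + i * gap_extend
    pX[i + 1, 1] <- 2L
  }
  for (j in seq_len(nb)) {
    Y[1, j + 1] <- gap_open + j * gap_extend
    pY[1, j + 1] <- 3L
  }
  for (i in seq_len(na)) {
    Mi1 <- M[i, ]; Xi1 <- X[i, ]; Yi1 <- Y[i, ]
    Mi <- M[i + 1, ]; Xi <- X[i + 1, ]; Yi <- Y[i + 1, ]
    pMi <- pM[i + 1, ]; pXi <- pX[i + 1, ]; pYi <- pY[i + 1, ]
    for (j in seq_len(nb)) {
      # match state
      cand <- c(Mi1[j], Xi1[j], Yi1[j])
      w <- which.max(cand)
      Mi[j + 1] <- cand[w] + S[i, j]
      pMi[j + 1] <- w
      # gap in B (consume A column i)
      cand <- c(Mi1[j + 1] + gap_open + gap_extend, Xi1[j + 1] + gap_extend)
      w <- which.max(cand)
      Xi[j + 1] <- cand[w]
      pXi[j + 1] <- c(1L, 2L)[w]
      # gap in A (consume B column j)
      cand <- c(Mi[j] + gap_open + gap_extend, Yi[j] + gap_extend)
      w <- which.max(cand)
      Yi[j + 1] <- cand[w]
      pYi[j + 1] <- c(1L, 3L)[w]
    }
    M[i + 1, ] <- Mi; X[i + 1, ] <- Xi; Y[i + 1, ] <- Yi
    pM[i + 1, ] <- pMi; pX[i + 1, ] <- pXi; pY[i + 1, ] <- pYi
  }
  finals <- c(M[na + 1, nb + 1], X[na + 1, nb + 1], Y[na + 1, nb + 1])
  state <- which.max(finals)
  score <- finals[state]
  # traceback
  i <- na; j <- nb
  pathA <- integer(0); pathB <- integer(0)  # 0 = gap, else source column
  while (i > 0 || j > 0) {
    if (state == 1L) {
      prev <- pM[i + 1, j + 1]
      pathA <- c(i, pathA); pathB <- c(j, pathB)
      i <- i - 1; j <- j - 1
      state <- prev
    } else if (state == 2L) {
      prev <- pX[i + 1, j + 1]
      pathA <- c(i, pathA); pathB <- c(0L, pathB)
      i <- i - 1
      state <- prev
    } else {
      prev <- pY[i + 1, j + 1]
      pathA <- c(0L, pathA); pathB <- c(j, pathB)
      j <- j - 1
      state <- prev
    }
  }
  ncols <- length(pathA)
  out <- matrix("-", nrow(matA) + nrow(matB), ncols)
  out[seq_len(nrow(matA)), pathA > 0] <- matA[, pathA[pathA > 0], drop = FALSE]
  out[nrow(matA) + seq_len(nrow(matB)), pathB > 0] <-
    matB[, pathB[pathB > 0], drop = FALSE]
  rownames(out) <- c(rownames(matA), rownames(matB))
  attr(out, "score") <- score
  out
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively: a guide tree is built by UPGMA on
#' cosine distances between 3-mer count vectors, then profiles are merged
#' bottom-up by global profile-profile alignment with affine gap costs.
#' Every input residue appears exactly once in its output row.
#'
#' @param seqs Named character vector of (ungapped) amino-acid sequences,
#'   length >= 2, no empty sequences.
#' @param submat 20 x 20 substitution score matrix (default BLOSUM62).
#' @param gap_open,gap_extend Negative gap penalties; a gap of length L
#'   scores `gap_open + L * gap_extend` (defaults -11 / -1).
#' @return An `aa_alignment` with rows in input order.
#' @export
progressive_align <- function(seqs, submat = blosum62(),
                              gap_open = -11, gap_extend = -1) {
  if (length(seqs) < 2L) stop_invalid("need at least 2 sequences")
  if (any(nchar(seqs) == 0L)) stop_invalid("empty sequence not allowed")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (gap_open > 0 || gap_extend > 0) {
    stop_invalid("gap penalties must be <= 0")
  }
  seqs <- toupper(ungap(seqs))
  mats <- lapply(seq_along(seqs), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  if (length(seqs) == 2L) {
    merged <- align_profiles(mats[[1]], mats[[2]], submat, gap_open, gap_extend)
  } else {
    D <- kmer_cosine_distances(seqs)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", length(seqs) + nrow(hc$merge))
    nodes[seq_along(seqs)] <- mats
    for (r in seq_len(nrow(hc$merge))) {
      pick <- function(v) if (v < 0) nodes[[-v]] else nodes[[length(seqs) + v]]
      nodes[[length(seqs) + r]] <- align_profiles(
        pick(hc$merge[r, 1]), pick(hc$merge[r, 2]),
        submat, gap_open, gap_extend)
    }
    merged <- nodes[[length(nodes)]]
  }
  aa_alignment(merged[names(seqs), , drop = FALSE])
}
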