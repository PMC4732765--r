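#' Protein multiple alignment container
#'
#' A light matrix-backed container for gapped amino-acid alignments. Rows are
#' sequences, columns alignment positions; `column_map` maps current columns
#' back to the coordinates of the untrimmed alignment so that trimmed
#' alignments stay addressable in original coordinates.
#'
#' @param x Named character vector of equal-length gapped sequences, or a
#'   character matrix with one residue per cell and rownames.
#' @param column_map Optional integer vector, one entry per column, strictly
#'   increasing; defaults to `1:ncol`.
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(x, column_map = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    n <- nchar(x)
    if (length(unique(n)) > 1L) {
      stop_invalid("all sequences must have equal length")
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  } else {
    stop_invalid("`x` must be a character vector or matrix")
  }
  if (is.null(column_map)) column_map <- seq_len(ncol(m))
  if (length(column_map) != ncol(m) || is.unsorted(column_map, strictly = TRUE)) {
    stop_invalid("`column_map` must be strictly increasing with one entry per column")
  }
  structure(list(mat = m, column_map = as.integer(column_map)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, n = 6, ...) {
  cat(sprintf("<aa_alignment> %d sequences x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  show <- head(seq_len(nrow(x$mat)), n)
  w <- min(60L, ncol(x$mat))
  for (i in show) {
    cat(sprintf("  %-15s %s%s\n", rownames(x$mat)[i],
                paste(x$mat[i, seq_len(w)], collapse = ""),
                if (ncol(x$mat) > w) "..." else ""))
  }
  if (nrow(x$mat) > n) cat(sprintf("  ... %d more\n", nrow(x$mat) - n))
  invisible(x)
}

#' @export
as.matrix.aa_alignment <- function(x, ...) x$mat

#' Alignment rows as gapped strings
#' @param aln An `aa_alignment`.
#' @return Named character vector of gapped sequences.
#' @export
aln_strings <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  out <- apply(aln$mat, 1, paste, collapse = "")
  names(out) <- rownames(aln$mat)
  out
}

#' @export
#' @importFrom tibble as_tibble tibble
as_tibble.aa_alignment <- function(x, ...) {
  tibble(label = rownames(x$mat),
         sequence = unname(apply(x$mat, 1, paste, collapse = "")))
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings FASTA IO returning plain named character
#' vectors (possibly gapped).
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "aa_alignment")) seqs <- aln_strings(seqs)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Percent identity between two gapped sequences
#'
#' Counts columns with identical residues (columns gapped in both sequences
#' are excluded) and divides by the chosen denominator: `"aligned_columns"`
#' (all columns where at least one sequence has a residue) or `"shorter"`
#' (the ungapped length of the shorter sequence, the convention of greedy
#' representative clustering).
#'
#' @param a,b Gapped sequences of equal length (as strings).
#' @param denominator `"aligned_columns"` or `"shorter"`.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, denominator = c("aligned_columns", "shorter")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) {
    stop_invalid("sequences must be aligned to equal length")
  }
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  both <- gap_a & gap_b
  ident <- sum(ca == cb & !both & !gap_a)
  denom <- switch(denominator,
    aligned_columns = sum(!both),
    shorter = min(sum(!gap_a), sum(!gap_b)))
  if (denom == 0) stop_invalid("percent identity undefined: zero denominator")
  100 * ident / denom
}

#' Remove gap-rich alignment columns
#'
#' Drops every column whose gap fraction exceeds `max_gap_frac` (strictly
#' greater by default, so a column at exactly the threshold is kept). The
#' `column_map` of the result indexes into the input's original coordinates.
#'
#' @param aln An `aa_alignment`.
#' @param max_gap_frac Maximum tolerated gap fraction in `[0, 1]` (default
#'   0.5: columns with more than 50% gaps are removed).
#' @param strict If `TRUE` remove on `> max_gap_frac`; if `FALSE` on `>=`.
#' @return Trimmed `aa_alignment`; attribute `"trim_report"` holds a tibble
#'   with per-column gap fraction and keep decision.
#' @export
trim_gappy_columns <- function(aln, max_gap_frac = 0.5, strict = TRUE) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (max_gap_frac < 0 || max_gap_frac > 1) {
    stop_invalid("`max_gap_frac` must be in [0, 1]")
  }
  gf <- colMeans(aln$mat == "-")
  keep <- if (strict) gf <= max_gap_frac else gf < max_gap_frac
  report <- tibble(column = aln$column_map, gap_fraction = unname(gf),
                   kept = unname(keep))
  out <- aa_alignment(aln$mat[, keep, drop = FALSE],
                      column_map = aln$column_map[keep])
  attr(out, "trim_report") <- report
  out
}

#' Ungap a sequence
#' @param x Gapped sequence string(s).
#' @return Sequence(s) with gap characters removed.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
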