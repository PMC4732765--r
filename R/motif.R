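# Active-site motif analysis: structure-anchored positions mapped through an
# alignment, 8-residue motif extraction and matching with residue
# equivalence classes, and sequence-logo information content.

#' Define an active-site motif
#'
#' The default is the 8-residue PriA-typical active-site motif
#' D-R-E-D-R-G-W-D with a `basic = {R, K}` equivalence class (a basic
#' residue can stand in for the arginine slots). Reference residue numbers
#' (structure numbering) are user configuration: only some of them are
#' typically anchored by a structure, so unresolved slots may be `NA`.
#'
#' @param residues Reference motif as a string or character vector (one
#'   letter per slot).
#' @param positions Optional integer vector of reference residue numbers,
#'   `NA` for unresolved slots; resolved entries must be strictly
#'   increasing.
#' @param equivalence Named list of residue equivalence classes.
#' @return A `motif_definition`.
#' @export
motif_definition <- function(residues = "DREDRGWD", positions = NULL,
                             equivalence = list(basic = c("R", "K"))) {
  slots <- if (length(residues) == 1L) strsplit(residues, "")[[1]] else residues
  if (is.null(positions)) positions <- rep(NA_integer_, length(slots))
  if (length(positions) != length(slots)) {
    stop_invalid("`positions` must have one entry per slot")
  }
  resolved <- positions[!is.na(positions)]
  if (length(resolved) > 1L && is.unsorted(resolved, strictly = TRUE)) {
    stop_invalid("resolved positions must be strictly increasing")
  }
  structure(list(slots = toupper(slots), positions = as.integer(positions),
                 equivalence = lapply(equivalence, toupper)),
            class = "motif_definition")
}

#' @export
print.motif_definition <- function(x, ...) {
  cat(sprintf("<motif_definition> %s\n", paste(x$slots, collapse = "-")))
  invisible(x)
}

#' Map reference residue positions to alignment columns
#'
#' Returns, for each 1-based residue number of the (ungapped) reference
#' sequence, the alignment column holding that residue — i.e. the column of
#' the k-th non-gap character of the reference row.
#'
#' @param aln An `aa_alignment`.
#' @param reference_row Row label of the reference sequence.
#' @param positions Integer vector of 1-based residue numbers.
#' @return Integer vector of alignment column indices.
#' @export
map_reference_positions <- function(aln, reference_row, positions) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!reference_row %in% rownames(aln$mat)) {
    stop_invalid("reference row '%s' not in alignment", reference_row)
  }
  row <- aln$mat[reference_row, ]
  residue_cols <- which(row != "-")
  if (any(positions < 1L) || any(positions > length(residue_cols))) {
    stop_invalid("position beyond reference length (%d residues)",
                 length(residue_cols))
  }
  residue_cols[positions]
}

#' Extract a motif from an alignment row
#'
#' @param aln An `aa_alignment`.
#' @param row Row label.
#' @param columns Alignment columns, in slot order (e.g. from
#'   [map_reference_positions()]).
#' @return The motif string (gaps appear as `-`).
#' @export
extract_motif <- function(aln, row, columns) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!row %in% rownames(aln$mat)) stop_invalid("row '%s' not in alignment", row)
  paste(aln$mat[row, columns], collapse = "")
}

#' Match an observed motif against a reference
#'
#' In `strict` mode a slot matches only on identity; in `equivalence` mode
#' it also matches when observed and reference residue belong to the same
#' equivalence class. A gap never matches.
#'
#' @param observed Observed motif string (same length as the reference).
#' @param reference A `motif_definition` (or reference string).
#' @param mode `"strict"` or `"equivalence"`.
#' @return List with `matches` (logical per slot) and `count` (0..n_slots).
#' @export
match_motif <- function(observed, reference = motif_definition(),
                        mode = c("strict", "equivalence")) {
  mode <- match.arg(mode)
  if (!inherits(reference, "motif_definition")) {
    reference <- motif_definition(reference)
  }
  obs <- strsplit(toupper(observed), "")[[1]]
  if (length(obs) != length(reference$slots)) {
    stop_invalid("observed motif must have %d letters",
                 length(reference$slots))
  }
  matches <- obs == reference$slots
  if (mode == "equivalence") {
    for (cls in reference$equivalence) {
      matches <- matches | (obs %in% cls & reference$slots %in% cls)
    }
  }
  matches[obs == "-"] <- FALSE
  list(matches = matches, count = sum(matches))
}

#' Sequence-logo information content of alignment columns
#'
#' For each column, the information content `R = log2(20) - H` with `H` the
#' Shannon entropy of the observed residue frequencies (gaps excluded from
#' the denominator; no small-sample correction), and per-letter heights
#' `frequency * R`.
#'
#' @param aln An `aa_alignment` (e.g. a phylum-specific cluster alignment).
#' @param columns Columns to profile (default: all).
#' @return Tibble: `slot` (1-based index into `columns`), `column`,
#'   `info_bits`, `letter`, `freq`, `height`. All-gap columns yield one row
#'   with `info_bits = NA` and no letters.
#' @export
logo_heights <- function(aln, columns = seq_len(ncol(aln$mat))) {
  stopifnot(inherits(aln, "aa_alignment"))
  purrr::map_dfr(seq_along(columns), function(k) {
    col <- aln$mat[, columns[k]]
    col <- col[!col %in% .missing_chars]
    if (length(col) == 0L) {
      return(tibble(slot = k, column = columns[k], info_bits = NA_real_,
                    letter = NA_character_, freq = NA_real_,
                    height = NA_real_))
    }
    f <- table(col) / length(col)
    H <- -sum(f * log2(f))
    R <- log2(20) - H
    tibble(slot = k, column = columns[k], info_bits = R,
           letter = names(f), freq = as.numeric(f),
           height = as.numeric(f) * R)
  })
}

#' Per-phylum motif occurrence table
#'
#' For every network member with taxonomy, extracts the motif at the given
#' alignment columns and counts, per phylum, how many members carry the full
#' reference motif (equivalence-mode match at every slot).
#'
#' @param network An `ssn` whose nodes carry a `phylum` column.
#' @param aln An `aa_alignment` containing every member as a row.
#' @param columns Mapped motif columns.
#' @param reference A `motif_definition`.
#' @return Tibble: `phylum`, `n_total`, `n_motif`, `pct` (percentage of the
#'   phylum's members carrying the motif).
#' @export
phylum_motif_table <- function(network, aln, columns,
                               reference = motif_definition()) {
  if (!"phylum" %in% names(network$nodes)) {
    stop_invalid("network nodes carry no `phylum` taxonomy")
  }
  members <- network$nodes |>
    dplyr::select("id", "phylum", "members") |>
    tidyr::unnest_longer("members", values_to = "member")
  members$full_match <- vapply(members$member, function(m) {
    mot <- extract_motif(aln, m, columns)
    match_motif(mot, reference, mode = "equivalence")$count ==
      length(reference$slots)
  }, logical(1))
  members |>
    dplyr::group_by(.data$phylum) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_motif = sum(.data$full_match)) |>
    dplyr::mutate(pct = 100 * .data$n_motif / .data$n_total) |>
    dplyr::arrange(.data$phylum)
}

#' Motif table for all alignment rows
#'
#' @param aln An `aa_alignment`.
#' @param columns Mapped motif columns.
#' @param reference A `motif_definition`.
#' @return Tibble: `id`, `motif`, `strict_count`, `equivalence_count`.
#' @export
motif_table <- function(aln, columns, reference = motif_definition()) {
  purrr::map_dfr(rownames(aln$mat), function(id) {
    mot <- extract_motif(aln, id, columns)
    tibble(id = id, motif = mot,
           strict_count = match_motif(mot, reference, "strict")$count,
           equivalence_count = match_motif(mot, reference,
                                           "equivalence")$count)
  })
}
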