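# Gene-neighborhood (operon) screening and species-wise concatenation.

#' Read a gene table
#'
#' Reads per-species gene annotations either from GFF3 (gene features with a
#' `gene=` attribute; gene order indices are assigned by start coordinate
#' within each contig) or from a tab-separated table with columns
#' `contig`, `gene_index`, `gene`, `strand`, `protein` (and optionally
#' `species_id`).
#'
#' @param path File path (`.gff`/`.gff3` or `.tsv`).
#' @param species_id Species label to attach (defaults to the file stem).
#' @return Tibble with columns `species_id`, `contig`, `gene_index`, `gene`,
#'   `strand` (and `protein` when the input provides it).
#' @export
read_gene_table <- function(path, species_id = NULL) {
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- ape::read.gff(path)
    g <- g[g$type == "gene", , drop = FALSE]
    gene <- sub(".*gene=([^;]+).*", "\\1", g$attributes)
    out <- tibble(species_id = species_id,
                  contig = as.character(g$seqid),
                  start = g$start,
                  gene = gene,
                  strand = as.character(g$strand)) |>
      dplyr::arrange(.data$contig, .data$start) |>
      dplyr::group_by(.data$contig) |>
      dplyr::mutate(gene_index = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("species_id", "contig", "gene_index", "gene", "strand")
    out
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"species_id" %in% names(tab)) tab$species_id <- species_id
    tibble::as_tibble(tab[, union(c("species_id", "contig", "gene_index",
                                    "gene", "strand"),
                                  names(tab))])
  }
}

#' Scan genomes for species with neighboring marker genes
#'
#' A species passes when all three marker genes lie on one contig and the
#' span of their gene-order indices (max - min + 1) minus 3 does not exceed
#' `max_intervening`. Internal order of the three genes is unconstrained;
#' strand agreement is optional. A species with a duplicated marker is
#' excluded with a warning; species missing a marker are silently excluded.
#'
#' @param gene_table Tibble as returned by [make_genomes()] or
#'   [read_gene_table()] (columns `species_id`, `contig`, `gene_index`,
#'   `gene`, `strand`).
#' @param marker_genes Three distinct gene names (default hisA/hisF/hisH).
#' @param max_intervening Maximum number of intervening genes (default 0:
#'   strict adjacency).
#' @param require_same_strand If `TRUE`, additionally require all three
#'   markers on the same strand.
#' @return Tibble, one row per species, sorted by `species_id`: columns
#'   `species_id`, `n_markers`, `span`, `included`, `reason`.
#' @export
scan_neighbor_triplets <- function(gene_table,
                                   marker_genes = c("hisA", "hisF", "hisH"),
                                   max_intervening = 0L,
                                   require_same_strand = FALSE) {
  if (length(unique(marker_genes)) != 3L) {
    stop_invalid("`marker_genes` must be three distinct names")
  }
  if (max_intervening < 0) stop_invalid("`max_intervening` must be >= 0")
  hits <- gene_table |>
    dplyr::filter(.data$gene %in% marker_genes)
  per_species <- split(hits, hits$species_id)
  res <- purrr::map_dfr(per_species, function(h) {
    sp <- h$species_id[1]
    if (anyDuplicated(h$gene)) {
      warn(sprintf("species '%s' excluded: duplicated marker gene", sp))
      return(tibble(species_id = sp, n_markers = length(unique(h$gene)),
                    span = NA_integer_, included = FALSE,
                    reason = "duplicated_marker"))
    }
    if (nrow(h) < 3L) {
      return(tibble(species_id = sp, n_markers = nrow(h), span = NA_integer_,
                    included = FALSE, reason = "missing_marker"))
    }
    by_contig <- split(h, h$contig)
    ok_contig <- purrr::keep(by_contig, ~ nrow(.x) == 3L)
    if (!length(ok_contig)) {
      return(tibble(species_id = sp, n_markers = 3L, span = NA_integer_,
                    included = FALSE, reason = "split_contigs"))
    }
    h1 <- ok_contig[[1]]
    span <- max(h1$gene_index) - min(h1$gene_index) + 1L
    ok <- (span - 3L) <= max_intervening
    reason <- if (!ok) "span_too_wide" else "ok"
    if (ok && require_same_strand && length(unique(h1$strand)) != 1L) {
      ok <- FALSE
      reason <- "strand_mismatch"
    }
    tibble(species_id = sp, n_markers = 3L, span = as.integer(span),
           included = ok, reason = reason)
  })
  # species never seen at all are absent from the input; keep deterministic order
  dplyr::arrange(res, .data$species_id)
}

#' Included species from a neighbor scan
#' @param scan Result of [scan_neighbor_triplets()].
#' @return Character vector of passing species ids.
#' @export
passing_species <- function(scan) scan$species_id[scan$included]

#' Concatenate marker-gene sequences species-wise
#'
#' Builds one concatenated record per species in the fixed gene order
#' HisF + HisA + HisH, recording the partition (gene, start, end; 1-based
#' inclusive on the concatenation) of each segment.
#'
#' @param sequences Named list mapping gene name to a named character vector
#'   of per-species protein sequences.
#' @param species Character vector of species to concatenate; each must have
#'   one sequence per gene.
#' @param gene_order Concatenation order (default `c("hisF","hisA","hisH")`).
#' @return Tibble with columns `species_id`, `sequence` and a `partitions`
#'   list-column of per-record tibbles (`gene`, `start`, `end`).
#' @export
concatenate_species <- function(sequences, species,
                                gene_order = c("hisF", "hisA", "hisH")) {
  if (!all(gene_order %in% names(sequences))) {
    stop_invalid("`sequences` must contain every gene in `gene_order`")
  }
  purrr::map_dfr(species, function(sp) {
    segs <- vapply(gene_order, function(g) {
      s <- sequences[[g]][[sp]]
      if (is.null(s) || is.na(s)) {
        stop_invalid("species '%s' lacks a sequence for gene '%s'", sp, g)
      }
      if (nchar(s) == 0L) {
        stop_invalid("species '%s': zero-length sequence for gene '%s'", sp, g)
      }
      s
    }, character(1))
    lens <- nchar(segs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    tibble(species_id = sp,
           sequence = paste(segs, collapse = ""),
           partitions = list(tibble(gene = gene_order,
                                    start = as.integer(starts),
                                    end = as.integer(ends))))
  })
}

#' Split a concatenated record back into gene segments
#' @param record One row of the [concatenate_species()] output.
#' @return Named character vector of gene segments.
#' @export
split_concatenation <- function(record) {
  parts <- record$partitions[[1]]
  out <- vapply(seq_len(nrow(parts)), function(i) {
    substr(record$sequence, parts$start[i], parts$end[i])
  }, character(1))
  names(out) <- parts$gene
  out
}

#' Export partitions as a NEXUS-style charset / TSV table
#' @param records Output of [concatenate_species()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_partitions <- function(records, path) {
  tab <- records |>
    dplyr::select("species_id", "partitions") |>
    tidyr::unnest("partitions")
  readr::write_tsv(tab, path)
  invisible(path)
}
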