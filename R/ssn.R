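# Sequence similarity networks: length filter, >95%-identity representative
# collapsing, all-by-all Smith-Waterman edges with Karlin-Altschul E-values,
# connected components and cluster statistics.

#' Filter sequences by length
#'
#' @param seqs Named character vector of sequences.
#' @param min_len,max_len Inclusive length window (defaults 230-260, the
#'   window that removes fragments from an isomerase-superfamily set).
#' @return The sequences whose lengths fall inside the window.
#' @export
filter_by_length <- function(seqs, min_len = 230L, max_len = 260L) {
  if (min_len > max_len) stop_invalid("`min_len` must be <= `max_len`")
  n <- nchar(seqs)
  seqs[n >= min_len & n <= max_len]
}

# global-alignment percent identity over the shorter sequence (the greedy
# clustering convention)
pid_shorter <- function(a, b, submat) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, gapOpening = 10, gapExtension = 1,
    type = "global")
  Biostrings::pid(pa, type = "PID3")
}

#' Collapse near-identical sequences into representatives
#'
#' Greedy incremental clustering: sequences are sorted longest-first; each
#' sequence joins the first existing representative whose global-alignment
#' identity (over the shorter sequence) is strictly greater than the
#' threshold, otherwise it founds a new cluster. With the default 95, only
#' pairs at more than 95% identity merge — a pair at exactly 95.0% does not.
#'
#' @param seqs Named character vector of sequences.
#' @param identity_threshold Percent identity threshold in (0, 100].
#' @param submat Substitution matrix for the global alignment.
#' @return Tibble with columns `representative`, `member`; attribute
#'   `"clusters"` maps representative to member vector.
#' @export
collapse_representatives <- function(seqs, identity_threshold = 95,
                                     submat = blosum62()) {
  if (identity_threshold <= 0 || identity_threshold > 100) {
    stop_invalid("`identity_threshold` must be in (0, 100]")
  }
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  assign_to <- character(length(seqs))
  names(assign_to) <- names(seqs)[ord]
  for (nm in names(seqs)[ord]) {
    hit <- NA_character_
    for (r in reps) {
      pid <- pid_shorter(seqs[[nm]], seqs[[r]], submat)
      # strict >, except that exact duplicates (100%) always merge, so a
      # threshold of 100 collapses only duplicates
      if (pid > identity_threshold || pid >= 100 - 1e-9) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, nm)
      hit <- nm
    }
    assign_to[nm] <- hit
  }
  out <- tibble(representative = unname(assign_to[names(seqs)]),
                member = names(seqs))
  attr(out, "clusters") <- split(out$member, out$representative)
  out
}

#' All-by-all similarity edges with Karlin-Altschul statistics
#'
#' Computes a Smith-Waterman local alignment for every pair of
#' representative sequences, converts the raw score S to a bit score
#' `S' = (lambda * S - ln K) / ln 2`, and to an E-value `E = m * n * 2^-S'`
#' with m, n the two sequence lengths (pairwise search space). Pairs with
#' `E <= evalue_cutoff` become undirected edges.
#'
#' @param seqs Named character vector of representative sequences.
#' @param submat Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 / 1).
#' @param lambda,K Karlin-Altschul parameters for the scoring system
#'   (defaults: published gapped BLOSUM62-11/1 values 0.267 and 0.041).
#' @param evalue_cutoff Maximum E-value for an edge (default 1e-54).
#' @return Tibble of edges: `from`, `to`, `score`, `bit_score`, `evalue`,
#'   `pid` (percent identity over aligned columns of the local alignment).
#' @export
allbyall_edges <- function(seqs, submat = blosum62(), gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041,
                           evalue_cutoff = 1e-54) {
  if (lambda <= 0 || K <= 0) stop_invalid("lambda and K must be > 0")
  nms <- names(seqs)
  n <- length(seqs)
  rows <- list()
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
        substitutionMatrix = submat, gapOpening = gap_open,
        gapExtension = gap_extend, type = "local")
      S <- Biostrings::score(pa)
      bit <- (lambda * S - log(K)) / log(2)
      E <- nchar(seqs[[i]]) * nchar(seqs[[j]]) * 2^(-bit)
      if (E <= evalue_cutoff) {
        rows[[length(rows) + 1L]] <- tibble(
          from = nms[i], to = nms[j], score = S, bit_score = bit,
          evalue = E, pid = Biostrings::pid(pa, type = "PID1"))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(from = character(), to = character(), score = numeric(),
                  bit_score = numeric(), evalue = numeric(), pid = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Build a sequence similarity network
#'
#' Full SSN construction: length filter, representative collapsing, and
#' all-by-all E-value edges between representatives. Node taxonomy can be
#' supplied as a tibble (`id`, plus ranked lineage columns such as
#' `superkingdom`, `phylum`, ...).
#'
#' @param seqs Named character vector of sequences.
#' @param taxonomy Optional tibble with an `id` column matching sequence
#'   names.
#' @param min_len,max_len Length window (inclusive).
#' @param identity_threshold Representative collapse threshold (percent).
#' @param evalue_cutoff Edge E-value cutoff.
#' @param ... Passed to [allbyall_edges()].
#' @return An `ssn` object: list with `nodes` (tibble: id, n_members,
#'   members list-col, sequence, plus taxonomy columns), `edges` (tibble),
#'   `parameters`.
#' @export
build_ssn <- function(seqs, taxonomy = NULL, min_len = 230L, max_len = 260L,
                      identity_threshold = 95, evalue_cutoff = 1e-54, ...) {
  kept <- filter_by_length(seqs, min_len, max_len)
  coll <- collapse_representatives(kept, identity_threshold)
  reps <- unique(coll$representative)
  members <- attr(coll, "clusters")[reps]
  nodes <- tibble(id = reps,
                  n_members = lengths(members),
                  members = unname(members),
                  sequence = unname(kept[reps]))
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes, taxonomy, by = "id")
  }
  edges <- allbyall_edges(kept[reps], evalue_cutoff = evalue_cutoff, ...)
  structure(list(nodes = nodes, edges = edges,
                 parameters = list(min_len = min_len, max_len = max_len,
                                   identity_threshold = identity_threshold,
                                   evalue_cutoff = evalue_cutoff)),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("<ssn> %d nodes (%d members), %d edges, E <= %g\n",
              nrow(x$nodes), sum(x$nodes$n_members), nrow(x$edges),
              x$parameters$evalue_cutoff))
  invisible(x)
}

ssn_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes["id"])
}

#' Connected components and per-cluster statistics
#'
#' Components of the network with, per component: representative count,
#' total member count, mean and sd of pairwise percent identity between the
#' component's representatives (global alignment, identity over aligned
#' columns; `NA` for singleton components), and the phylum composition when
#' taxonomy is present.
#'
#' @param network An `ssn`.
#' @return Tibble, one row per component, ordered by decreasing size:
#'   `component`, `n_nodes`, `n_members`, `mean_pid`, `sd_pid`, `phyla`
#'   (list-col of count tables when taxonomy is available).
#' @export
components_and_stats <- function(network) {
  g <- ssn_graph(network)
  comp <- igraph::components(g)
  membership <- comp$membership[network$nodes$id]
  submat <- blosum62()
  purrr::map_dfr(order(-comp$csize), function(ci) {
    ids <- network$nodes$id[membership == ci]
    nd <- network$nodes[network$nodes$id %in% ids, ]
    pids <- NULL
    if (length(ids) >= 2L) {
      prs <- utils::combn(ids, 2)
      pids <- vapply(seq_len(ncol(prs)), function(k) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(network$nodes$sequence[
            network$nodes$id == prs[1, k]]),
          Biostrings::AAString(network$nodes$sequence[
            network$nodes$id == prs[2, k]]),
          substitutionMatrix = submat, gapOpening = 10, gapExtension = 1,
          type = "global")
        Biostrings::pid(pa, type = "PID1")
      }, numeric(1))
    }
    tibble(component = ci,
           n_nodes = length(ids),
           n_members = sum(nd$n_members),
           mean_pid = if (is.null(pids)) NA_real_ else mean(pids),
           sd_pid = if (is.null(pids) || length(pids) < 2L) NA_real_
                    else sd(pids),
           phyla = list(if ("phylum" %in% names(nd))
             table(nd$phylum) else NULL))
  })
}

#' Write an SSN as GraphML
#'
#' Node attributes: member count and any taxonomy/annotation columns; edge
#' attributes: E-value and percent identity. Loadable by standard graph
#' viewers.
#'
#' @param network An `ssn`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ssn_graphml <- function(network, path) {
  vattr <- network$nodes[, !vapply(network$nodes, is.list, logical(1))]
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = vattr)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
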