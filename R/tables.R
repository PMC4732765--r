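# Bundled reference tables: published steady-state kinetic constants and in
# vivo complementation times for extant and reconstructed HisA/PriA enzymes,
# and the per-phylum species counts behind the concatenated alignment. These
# are inputs (small plain-text tables shipped with the package), used for
# bookkeeping checks and rank-concordance analyses.

.extdata <- function(file) {
  system.file("extdata", file, package = "hisatrace", mustWork = TRUE)
}

#' Published steady-state kinetic constants
#'
#' Turnover numbers and Michaelis constants of extant PriA/HisA enzymes and
#' reconstructed ancestors, for the HisA (ProFAR isomerization) and TrpF
#' (PRA isomerization) reactions. Where kcat and KM could not be determined
#' individually, only the printed efficiency is available
#' (`eff_printed_Ms`). Catalytic efficiencies are otherwise computed from
#' kcat and KM.
#'
#' @return Tibble: `enzyme`, `reaction`, `kcat_s`, `KM_uM`,
#'   `eff_printed_Ms`, `eff_Ms` (computed at 2 significant figures).
#' @export
extant_kinetics <- function() {
  tab <- readr::read_tsv(.extdata("extant_kinetics.tsv"),
                         show_col_types = FALSE)
  dplyr::mutate(tab, eff_Ms = dplyr::if_else(
    is.na(.data$kcat_s), .data$eff_printed_Ms,
    catalytic_efficiency(.data$kcat_s, .data$KM_uM)))
}

#' In vivo complementation times
#'
#' Mean times (hours) to visible colonies of auxotrophic deletion strains
#' complemented by each enzyme; `NA` means no growth.
#'
#' @return Tibble: `enzyme`, `delta_hisA_h`, `delta_trpF_h`,
#'   `delta_hisA_trpF_h`.
#' @export
complementation_times <- function() {
  readr::read_tsv(.extdata("complementation_times.tsv"),
                  show_col_types = FALSE)
}

#' Per-phylum species counts of the concatenated set
#'
#' Number of species per phylum/class whose hisA, hisF and hisH genes are
#' genome neighbors, including the separately selected actinobacterial sets.
#'
#' @return Tibble: `phylum`, `n_species`.
#' @export
phylum_counts <- function() {
  readr::read_tsv(.extdata("phylum_counts.tsv"), show_col_types = FALSE)
}
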