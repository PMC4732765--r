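# End-to-end orchestration on synthetic data: simulate -> scan ->
# concatenate -> align/trim -> tree + diagnostics -> ASR -> SSN -> motifs ->
# kinetics, from a single validated config, with a manifest of parameters,
# seed and output checksums.

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. Defaults
#' follow the published analysis settings where those are stated (gap
#' threshold 0.5, identity collapse 95, E-value cutoff 1e-54, length window
#' 230-260, 4 chains, burnin fraction 0.1); simulation sizes default to desk
#' scale.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory.
#' @param n_species Number of simulated species.
#' @param neighbor_fraction Fraction of genomes with adjacent
#'   hisA/hisF/hisH.
#' @param root_lengths Named lengths of the simulated hisF/hisA/hisH
#'   proteins.
#' @param divergence Tree depth scaling (expected substitutions per site).
#' @param indel_rate Indel events per site per unit branch length.
#' @param gap_threshold Column gap fraction above which columns are trimmed.
#' @param identity_collapse Representative collapse threshold (percent).
#' @param evalue_cutoff SSN edge E-value cutoff.
#' @param length_window SSN length filter `c(min, max)`; `NULL` disables.
#' @param chains,samples,burnin_frac MCMC settings.
#' @param model Substitution model name ("JTT" or "WAG").
#' @param motif_positions Reference residue numbers of the motif slots on
#'   the simulated hisA reference.
#' @param kinetics List: kcat, KM, E0, S0_list, noise_sd, dt, t_end.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("hisatrace_run_"),
                            n_species = 12L, neighbor_fraction = 0.75,
                            root_lengths = c(hisF = 90L, hisA = 110L,
                                             hisH = 70L),
                            divergence = 0.4, indel_rate = 0.02,
                            gap_threshold = 0.5, identity_collapse = 95,
                            evalue_cutoff = 1e-54, length_window = NULL,
                            chains = 4L, samples = 400L, burnin_frac = 0.1,
                            model = "JTT",
                            motif_positions = c(10, 25, 40, 55, 70, 85,
                                                95, 105),
                            kinetics = list(kcat = 0.9, KM = 28, E0 = 0.05,
                                            S0_list = c(5, 10, 20, 40, 80),
                                            noise_sd = 0.05, dt = 5,
                                            t_end = 2000)) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$identity_collapse <= 0 || cfg$identity_collapse > 100) {
    stop_invalid("identity_collapse must be in (0, 100]")
  }
  if (cfg$neighbor_fraction < 0 || cfg$neighbor_fraction > 1) {
    stop_invalid("neighbor_fraction must be in [0, 1]")
  }
  if (cfg$gap_threshold < 0 || cfg$gap_threshold > 1) {
    stop_invalid("gap_threshold must be in [0, 1]")
  }
  if (cfg$n_species < 4L) stop_invalid("n_species must be >= 4")
  if (cfg$chains < 2L) stop_invalid("chains must be >= 2 for diagnostics")
  if (cfg$burnin_frac < 0 || cfg$burnin_frac >= 1) {
    stop_invalid("burnin_frac must be in [0, 1)")
  }
  if (!cfg$model %in% c("JTT", "WAG")) stop_invalid("unknown model")
  if (!all(c("hisF", "hisA", "hisH") %in% names(cfg$root_lengths))) {
    stop_invalid("root_lengths must name hisF, hisA and hisH")
  }
  with(cfg$kinetics, {
    if (any(c(kcat, KM, E0, S0_list, dt) <= 0)) {
      stop_invalid("kinetic parameters must be > 0")
    }
  })
  invisible(cfg)
}

#' Load a pipeline config from YAML/JSON
#' @param path Config file path.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$root_lengths)) raw$root_lengths <- unlist(raw$root_lengths)
  args <- utils::modifyList(raw, list(...))
  do.call(pipeline_config, args)
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order, writes all artifacts (FASTA,
#' newick, TSV) plus a JSON manifest (parameters, seed, md5 checksums) to
#' the output directory, and returns the in-memory results. Reruns with the
#' same config and seed reproduce the sequence/tree outputs byte-for-byte.
#'
#' @param config A `pipeline_config`, or a path to a YAML/JSON config.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list()

  say("[simulate] %d species, divergence %.2g", cfg$n_species,
      cfg$divergence)
  model <- aa_model(cfg$model)
  tree <- sample_yule_tree(cfg$n_species, birth_rate = 1, seed = cfg$seed)
  tree$edge.length <- tree$edge.length * cfg$divergence /
    max(ape::node.depth.edgelength(tree))
  fams <- lapply(seq_along(cfg$root_lengths), function(i) {
    evolve_alignment(tree, cfg$root_lengths[i], model,
                     indel_rate = cfg$indel_rate,
                     seed = cfg$seed + 17L * i)
  })
  names(fams) <- names(cfg$root_lengths)
  gene_seqs <- lapply(fams, function(f) ungap(aln_strings(f$alignment)))
  res$families <- fams
  genomes <- make_genomes(gene_seqs, cfg$neighbor_fraction,
                          decoy_genes = 10L, seed = cfg$seed + 101L)
  res$genomes <- genomes

  say("[scan] neighbor triplets (max_intervening 0)")
  scan <- scan_neighbor_triplets(genomes)
  res$scan <- scan
  passing <- passing_species(scan)
  if (length(passing) < 4L) {
    stop("stage 'scan' failed: fewer than 4 species pass the neighbor scan")
  }
  concat <- concatenate_species(gene_seqs, passing)
  res$concatenations <- concat

  say("[align] %d concatenations", nrow(concat))
  seqs <- stats::setNames(concat$sequence, concat$species_id)
  aln <- progressive_align(seqs)
  trimmed <- trim_gappy_columns(aln, cfg$gap_threshold)
  res$alignment <- trimmed

  say("[tree] ML search + %d MCMC chains x %d", cfg$chains, cfg$samples)
  ml <- nni_ml_search(nj_tree(ml_distances(trimmed, model)), trimmed, model)
  run <- mcmc_sample(trimmed, model, n_chains = cfg$chains,
                     n_samples = cfg$samples,
                     burnin_frac = cfg$burnin_frac, seed = cfg$seed + 7L)
  res$ml_tree <- ml
  res$mcmc <- run
  res$diagnostics <- glance(run)
  res$consensus <- consensus_with_support(run)
  say("[tree] maxdiff %.3f, min ESS %.0f", res$diagnostics$maxdiff,
      res$diagnostics$min_ess_loglik)

  say("[asr] marginal reconstruction")
  rooted <- phangorn::midpoint(ml)
  rooted$node.label <- paste0("N", seq_len(rooted$Nnode))
  recon <- ancestral_reconstruction(rooted, trimmed, model)
  res$asr <- recon

  say("[ssn] hisA family network")
  his_a <- gene_seqs$hisA
  window <- cfg$length_window
  taxonomy <- tibble(id = names(his_a),
                     phylum = paste0("cladeA"))
  # phylum labels: split at the true tree's root
  root_kids <- tree$edge[tree$edge[, 1] == length(tree$tip.label) + 1L, 2]
  left <- if (root_kids[1] <= length(tree$tip.label)) {
    tree$tip.label[root_kids[1]]
  } else ape::extract.clade(tree, root_kids[1])$tip.label
  taxonomy$phylum <- ifelse(taxonomy$id %in% left, "cladeA", "cladeB")
  net <- build_ssn(his_a, taxonomy = taxonomy,
                   min_len = if (is.null(window)) 1L else window[1],
                   max_len = if (is.null(window)) 10000L else window[2],
                   identity_threshold = cfg$identity_collapse,
                   evalue_cutoff = cfg$evalue_cutoff)
  res$ssn <- net
  res$components <- components_and_stats(net)

  say("[motif] mapped positions + logos")
  ha_aln <- fams$hisA$alignment
  ref_row <- rownames(ha_aln$mat)[1]
  cols <- map_reference_positions(ha_aln, ref_row,
                                  cfg$motif_positions)
  ref_motif <- motif_definition(extract_motif(ha_aln, ref_row, cols))
  res$motifs <- motif_table(ha_aln, cols, ref_motif)
  res$logo <- logo_heights(ha_aln, cols)

  say("[kinetics] progress-curve fit")
  k <- cfg$kinetics
  curves <- simulate_progress_curves(k$kcat, k$KM, k$E0, k$S0_list,
                                     noise_sd = k$noise_sd, dt = k$dt,
                                     t_end = k$t_end,
                                     seed = cfg$seed + 29L)
  fit <- fit_progress_curves(curves, model = "plain")
  res$kinetics <- fit
  eff <- stats::setNames(extant_kinetics() |>
                           dplyr::filter(.data$reaction == "TrpF",
                                         grepl("^CA-", .data$enzyme)) |>
                           dplyr::pull(.data$eff_Ms),
                         c("CA-Act-HisA", "CA-Prot-HisA", "CA-Bact-HisA"))
  tms <- complementation_times()
  times <- stats::setNames(tms$delta_trpF_h, tms$enzyme)
  res$concordance <- rank_concordance(eff, times)

  say("[write] artifacts + manifest")
  paths <- c(
    alignment = file.path(cfg$outdir, "alignment_trimmed.fasta"),
    ml_tree = file.path(cfg$outdir, "ml_tree.nwk"),
    consensus = file.path(cfg$outdir, "consensus.nwk"),
    ancestors = file.path(cfg$outdir, "ancestors.fasta"),
    curves = file.path(cfg$outdir, "progress_curves.tsv"),
    motifs = file.path(cfg$outdir, "motif_table.tsv"),
    scan = file.path(cfg$outdir, "neighbor_scan.tsv"))
  write_fasta(trimmed, paths[["alignment"]])
  ape::write.tree(ml, paths[["ml_tree"]])
  ape::write.tree(res$consensus$tree, paths[["consensus"]])
  write_fasta(stats::setNames(recon$nodes$ml_sequence, recon$nodes$node),
              paths[["ancestors"]])
  readr::write_tsv(curves, paths[["curves"]])
  readr::write_tsv(res$motifs, paths[["motifs"]])
  readr::write_tsv(scan, paths[["scan"]])
  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("outdir"))],
    outputs = as.list(stats::setNames(tools::md5sum(unname(paths)),
                                      basename(unname(paths)))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
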