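test_that("reference positions map through gaps and round-trip", {
  aln <- aa_alignment(c(ref = "A-CD", other = "AXCD"))
  expect_equal(map_reference_positions(aln, "ref", 2), 3L)
  g <- aa_alignment(c(ref = "ACDEF"))
  expect_equal(map_reference_positions(g, "ref", 1:5), 1:5)
  # reading the reference at mapped columns reproduces its residues
  aln2 <- aa_alignment(c(ref = "M-K--TAYI", x = "MGKLLTAYI"))
  cols <- map_reference_positions(aln2, "ref", 1:6)
  expect_equal(extract_motif(aln2, "ref", cols), "MKTAYI")
  expect_error(map_reference_positions(aln, "ref", 4),
               class = "hisatrace_invalid_argument")
})

test_that("motif extraction reads slots in order, gaps included", {
  rows <- c(pria = "DREDRGWD", tmlike = "DREDKGWD", gapped = "DRE-RGWD")
  aln <- aa_alignment(rows)
  cols <- 1:8
  expect_equal(extract_motif(aln, "pria", cols), "DREDRGWD")
  expect_equal(extract_motif(aln, "tmlike", cols), "DREDKGWD")
  expect_equal(extract_motif(aln, "gapped", cols), "DRE-RGWD")
})

test_that("motif matching distinguishes strict and equivalence modes", {
  ref <- motif_definition("DREDRGWD")
  # ancestral-type motif: Lys at slots 3 and 5 -> 6/8 strict
  expect_equal(match_motif("DRKDKGWD", ref, "strict")$count, 6)
  # tmHisA-type: Lys for Arg at slot 5 -> 7 strict, 8 with basic class
  expect_equal(match_motif("DREDKGWD", ref, "strict")$count, 7)
  expect_equal(match_motif("DREDKGWD", ref, "equivalence")$count, 8)
  expect_equal(match_motif("DREDRGWD", ref, "strict")$count, 8)
  expect_equal(match_motif("DREDRGWD", ref, "equivalence")$count, 8)
  # gaps never match
  expect_equal(match_motif("DRED-GWD", ref, "equivalence")$count, 7)
  expect_error(match_motif("DRED", ref), class = "hisatrace_invalid_argument")
  # strict matching is symmetric in observed/reference
  obs <- "DRKDKGWD"
  expect_equal(match_motif(obs, motif_definition("DREDRGWD"), "strict")$count,
               match_motif("DREDRGWD", motif_definition(obs),
                           "strict")$count)
})

test_that("motif definitions validate their slot positions", {
  expect_silent(motif_definition("DREDRGWD",
                                 positions = c(NA, NA, 109, NA, 143, NA,
                                               145, NA)))
  expect_error(motif_definition("DREDRGWD",
                                positions = c(NA, NA, 143, NA, 109, NA,
                                              145, NA)),
               class = "hisatrace_invalid_argument")
})

test_that("logo information content is exact on reference columns", {
  inv <- aa_alignment(c(a = "D", b = "D", c = "D", d = "D"))
  l1 <- logo_heights(inv)
  expect_equal(l1$info_bits, log2(20), tolerance = 1e-12)
  expect_equal(l1$height, log2(20), tolerance = 1e-12)

  unif <- aa_alignment(stats::setNames(aa_states(), paste0("s", 1:20)))
  l2 <- logo_heights(unif)
  expect_equal(unique(round(l2$info_bits, 12)), 0)

  half <- aa_alignment(c(a = "D", b = "D", c = "E", d = "E"))
  l3 <- logo_heights(half)
  expect_equal(l3$info_bits, rep(log2(20) - 1, 2), tolerance = 1e-12)
  expect_equal(sort(l3$letter), c("D", "E"))

  # gaps are excluded from the denominator; all-gap columns give NA
  gappy <- aa_alignment(c(a = "D-", b = "D-", c = "--", d = "E-"))
  l4 <- logo_heights(gappy)
  expect_equal(l4$freq[l4$column == 1 & l4$letter == "D"], 2 / 3)
  expect_true(is.na(l4$info_bits[l4$column == 2]))

  # information is bounded and duplication never changes frequencies
  fam <- evolve_alignment(sample_yule_tree(5, 1, 6), 30, seed = 2)
  lh <- logo_heights(fam$alignment)
  expect_true(all(lh$info_bits >= -1e-12 & lh$info_bits <= log2(20) + 1e-12))
  doubled <- aa_alignment(fam$alignment$mat[rep(1:5, 2), ])
  expect_equal(logo_heights(doubled)$freq, lh$freq)
})

test_that("per-phylum motif fractions count equivalence-mode full matches", {
  n_prot <- 20
  carriers <- 3
  rows <- c(
    stats::setNames(rep("DREDRGWD", carriers), paste0("p", 1:carriers)),
    stats::setNames(rep("DAADAGAA", n_prot - carriers),
                    paste0("p", (carriers + 1):n_prot)),
    stats::setNames(rep("DREDKGWD", 5), paste0("b", 1:5)))
  aln <- aa_alignment(rows)
  nodes <- tibble::tibble(
    id = names(rows), n_members = 1L,
    members = as.list(names(rows)),
    sequence = unname(rows),
    phylum = c(rep("Proteobacteria", n_prot), rep("Bacteroidetes", 5)))
  net <- structure(list(nodes = nodes,
                        edges = tibble::tibble(from = character(),
                                               to = character()),
                        parameters = list()), class = "ssn")
  tab <- phylum_motif_table(net, aln, 1:8)
  prot <- tab[tab$phylum == "Proteobacteria", ]
  expect_equal(prot$n_motif, carriers)
  expect_equal(prot$pct, 100 * carriers / n_prot)
  # equivalence mode: the Lys-for-Arg motif still counts as a full match
  bact <- tab[tab$phylum == "Bacteroidetes", ]
  expect_equal(bact$n_motif, 5L)
  # motif + non-motif partitions each phylum completely
  expect_equal(tab$n_total, c(5L, n_prot))
})

test_that("motif columns on the true ancestor equal direct indexing", {
  fam <- evolve_alignment(sample_yule_tree(6, 1, 9), 60, indel_rate = 0.05,
                          seed = 12)
  anc_aln <- fam$ancestor_alignment
  positions <- c(3, 10, 20, 30, 40, 45, 50, 55)
  cols <- map_reference_positions(anc_aln, "N1", positions)
  mot <- extract_motif(anc_aln, "N1", cols)
  direct <- paste(strsplit(fam$true_ancestors[["N1"]], "")[[1]][positions],
                  collapse = "")
  expect_equal(mot, direct)
})
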