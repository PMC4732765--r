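test_that("pruning likelihood matches limits and the enumeration oracle", {
  m <- aa_model("JTT")
  # zero-length two-leaf tree, both 'A': likelihood = pi_A
  tr0 <- ape::read.tree(text = "(t1:0,t2:0);")
  aln0 <- aa_alignment(c(t1 = "A", t2 = "A"))
  expect_equal(tree_log_likelihood(tr0, aln0, m),
               log(m$freqs[match("A", aa_states())]), tolerance = 1e-10)

  # 4-taxon, 5 columns: equals brute-force enumeration
  tr <- four_taxon_tree()
  mat <- rbind(t1 = c("A", "R", "W", "K", "A"),
               t2 = c("A", "K", "W", "K", "C"),
               t3 = c("R", "R", "W", "E", "A"),
               t4 = c("A", "R", "F", "K", "A"))
  aln <- aa_alignment(mat)
  bf <- sum(vapply(seq_len(ncol(mat)), function(j) {
    log(brute_force_column(tr, mat[, j], m)$likelihood)
  }, numeric(1)))
  expect_equal(tree_log_likelihood(tr, aln, m), bf, tolerance = 1e-8)

  # saturating branch lengths: leaves become independent draws from pi
  trinf <- tr
  trinf$edge.length[] <- 400
  indep <- sum(log(m$freqs[match(mat, aa_states())]))
  expect_equal(tree_log_likelihood(trinf, aln, m), indep, tolerance = 1e-6)

  expect_error(tree_log_likelihood(tr, aa_alignment(c(x = "A", y = "A",
                                                      z = "A", w = "A")), m),
               class = "hisatrace_invalid_argument")
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  m <- aa_model("JTT", alpha = 0.7)
  fam <- evolve_alignment(sample_yule_tree(6, 1, 2), 100, seed = 5)
  tr <- ape::unroot(fam$tree)
  ll <- tree_log_likelihood(tr, fam$alignment, m)
  for (og in c("t1", "t3")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_log_likelihood(rr, fam$alignment, m), ll,
                 tolerance = 1e-8)
  }
})

test_that("gamma mixing averages categories in likelihood space", {
  fam <- evolve_alignment(sample_yule_tree(4, 1, 6), 40, seed = 1)
  tr <- fam$tree
  aln <- fam$alignment
  mg <- aa_model("JTT", alpha = 0.5, n_categories = 4)
  rates <- gamma_rates(0.5, 4)
  per_cat <- vapply(rates, function(r) {
    sc <- tr
    sc$edge.length <- sc$edge.length * r
    tree_log_likelihood(sc, aln, aa_model("JTT"))
  }, numeric(1))
  # single-column check would be exact; whole-alignment mixing must sit
  # between min and max of the per-category log-likelihoods
  ll <- tree_log_likelihood(tr, aln, mg)
  expect_gte(ll, min(per_cat) - 1e-9)
  expect_lte(ll, max(per_cat) + log(1))
})

test_that("NJ recovers additive distances exactly and star trees collapse", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  # generating topology: AB | CD
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # additive: path distances reproduced exactly
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-10)

  aln <- aa_alignment(c(a = "MKL", b = "MKL", c = "MKL"))
  d0 <- ml_distances(aln)
  expect_true(all(d0 == 0))
  expect_error(nj_tree(d0[1:2, 1:2]), class = "hisatrace_invalid_argument")
})

test_that("ML distances recover pairwise divergence", {
  m <- aa_model("JTT")
  tr <- ape::read.tree(text = "(t1:0.15,t2:0.15);")
  fam <- evolve_alignment(tr, 3000, m, seed = 8)
  d <- ml_distances(fam$alignment, m)
  expect_equal(d["t1", "t2"], 0.3, tolerance = 0.1)
})

test_that("NNI search keeps the true topology and never decreases the likelihood", {
  m <- aa_model("JTT")
  tr <- sample_yule_tree(5, 1, 12)
  tr$edge.length <- tr$edge.length * 0.3 / max(tr$edge.length)
  fam <- evolve_alignment(tr, 400, m, indel_rate = 0, seed = 3)
  start <- ape::unroot(fam$tree)
  ll0 <- tree_log_likelihood(start, fam$alignment, m)
  out <- nni_ml_search(start, fam$alignment, m)
  expect_gte(attr(out, "loglik"), ll0)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(out), start)), 0)
})

test_that("NNI search recovers the true 4-taxon split from simulated data", {
  m <- aa_model("JTT")
  wins <- 0
  for (i in 1:20) {
    tr <- four_taxon_tree(rep(0.2, 6))
    fam <- evolve_alignment(tr, 500, m, indel_rate = 0, seed = 100 + i)
    d <- ml_distances(fam$alignment, m)
    # start from a wrong topology to make the move necessary
    start <- ape::read.tree(text = paste0(
      "((t1:0.2,t3:0.2):0.2,(t2:0.2,t4:0.2):0.2);"))
    out <- nni_ml_search(ape::unroot(start), fam$alignment, m)
    ok <- ape::is.monophyletic(ape::root(out, "t4"), c("t1", "t2"))
    wins <- wins + ok
  }
  expect_gte(wins, 18)
})

test_that("outgroup rooting splits the separating branch 50:50", {
  tr <- ape::unroot(ape::read.tree(text = "((A:1,B:1):0.4,(C:1,D:1):0.6);"))
  r <- root_with_outgroup(tr, c("A", "B"))
  expect_true(ape::is.rooted(r))
  root_edges <- which(r$edge[, 1] == length(r$tip.label) + 1L)
  lens <- r$edge.length[root_edges]
  expect_equal(lens[1], lens[2])
  expect_error(root_with_outgroup(tr, c("A", "C")), "A, C")
  # single-leaf outgroup roots on the pendant branch
  r1 <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(r1))
  expect_equal(sum(r1$edge.length), sum(tr$edge.length))
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")),
               class = "hisatrace_invalid_argument")
})

test_that("branch lengths are recovered on the true topology", {
  m <- aa_model("JTT")
  tr <- four_taxon_tree(c(0.2, 0.25, 0.15, 0.3, 0.2, 0.15))
  fam <- evolve_alignment(tr, 2000, m, indel_rate = 0, seed = 21)
  # only the unrooted tree's branch lengths are identifiable (the two root
  # edges trade off freely under a reversible model)
  true_u <- ape::unroot(tr)
  start <- true_u
  start$edge.length[] <- 0.1
  opt <- optimize_branch_lengths(start, fam$alignment, m)
  expect_equal(opt$edge.length, true_u$edge.length, tolerance = 0.15)
})
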