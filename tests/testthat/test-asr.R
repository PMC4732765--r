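test_that("marginal residue posteriors equal the enumeration oracle", {
  m <- aa_model("JTT")
  tr <- four_taxon_tree()
  col <- c(t1 = "A", t2 = "K", t3 = "R", t4 = "A")
  post <- marginal_posteriors(tr, column_alignment(col), m)
  bf <- brute_force_posteriors(tr, col, m)
  # internal nodes are N1 (root), N2, N3 in the enumeration's node order
  for (k in 1:3) {
    expect_lt(max(abs(post[[c("N1", "N2", "N3")[k]]][, 1] - bf[[k]])), 1e-8)
  }
  # posterior mass conservation at every node
  for (p in post) expect_equal(unname(colSums(p)), rep(1, ncol(p)),
                               tolerance = 1e-9)
  expect_error(marginal_posteriors(ape::unroot(tr), column_alignment(col), m),
               class = "hisatrace_invalid_argument")
})

test_that("degenerate branch lengths give certainty or the prior", {
  m <- aa_model("JTT")
  tr0 <- four_taxon_tree(rep(1e-9, 6))
  col <- c(t1 = "K", t2 = "K", t3 = "K", t4 = "K")
  post <- marginal_posteriors(tr0, column_alignment(col), m)
  expect_equal(unname(post$N1["K", 1]), 1, tolerance = 1e-6)

  # a node whose child branches saturate carries no signal: posterior ~ pi
  trinf <- ape::read.tree(text =
    "((t1:300,t2:300)N2:300,(t3:0.1,t4:0.1)N3:0.1)N1;")
  post2 <- marginal_posteriors(trinf, column_alignment(col), m)
  expect_equal(unname(post2$N2[, 1]), unname(m$freqs), tolerance = 1e-6)
})

test_that("root posterior is consistent with the plain pruning pass", {
  m <- aa_model("JTT")
  fam <- evolve_alignment(sample_yule_tree(5, 1, 23), 30, seed = 2)
  post <- marginal_posteriors(fam$tree, fam$alignment, m)
  pat <- hisatrace:::site_patterns(
    hisatrace:::encode_alignment(fam$alignment, m))
  up <- hisatrace:::.prune_up(fam$tree, pat, m)
  direct <- sweep(m$freqs * up$partial[[up$root]], 2,
                  colSums(m$freqs * up$partial[[up$root]]), "/")
  expect_lt(max(abs(post$N1 - direct[, pat$col_to_pattern])), 1e-9)
})

test_that("indel reconstruction matches the two-state oracle", {
  pm <- presence_model(1)
  tr <- four_taxon_tree()
  # gap-free column: presence near-certain everywhere (a short-branch CTMC
  # leaves a vanishing probability of a double flip)
  aln_full <- aa_alignment(c(t1 = "K", t2 = "K", t3 = "K", t4 = "K"))
  pres <- reconstruct_indels(aln_full, tr)
  expect_true(all(vapply(pres, function(p) all(p > 0.9), logical(1))))
  bin_full <- c(t1 = "1", t2 = "1", t3 = "1", t4 = "1")
  bf_full <- brute_force_posteriors(tr, bin_full, pm)
  for (k in 1:3) {
    expect_equal(pres[[c("N1", "N2", "N3")[k]]][1], bf_full[[k]][2],
                 tolerance = 1e-8)
  }

  # all-gap column: presence posterior below 0.5 everywhere
  aln_gap <- aa_alignment(c(t1 = "-", t2 = "-", t3 = "-", t4 = "-"))
  pres0 <- reconstruct_indels(aln_gap, tr)
  for (id in c("N1", "N2", "N3")) expect_lt(pres0[[id]][1], 0.5)

  # mixed column: equals enumeration over internal 0/1 assignments
  aln_mix <- aa_alignment(c(t1 = "K", t2 = "-", t3 = "K", t4 = "-"))
  pres_mix <- reconstruct_indels(aln_mix, tr)
  bin <- c(t1 = "1", t2 = "0", t3 = "1", t4 = "0")
  bf <- brute_force_posteriors(tr, bin, pm)
  for (k in 1:3) {
    expect_equal(pres_mix[[c("N1", "N2", "N3")[k]]][1], bf[[k]][2],
                 tolerance = 1e-8)
  }
})

test_that("most-likely sequences favor presence at ties and break argmax ties alphabetically", {
  m <- aa_model("JTT")
  fam <- evolve_alignment(sample_yule_tree(5, 1, 3), 40, indel_rate = 0.05,
                          seed = 6)
  rec <- ancestral_reconstruction(fam$tree, fam$alignment, m)
  expect_equal(nchar(rec$nodes$ml_sequence[1]), ncol(fam$alignment$mat))
  # emitted residues are the column argmax wherever presence >= 0.5
  id <- "N1"
  chars <- strsplit(rec$nodes$ml_sequence[rec$nodes$node == id], "")[[1]]
  pres <- rec$presence_posteriors[[id]]
  for (j in seq_along(chars)) {
    if (pres[j] >= 0.5) {
      col <- rec$residue_posteriors[[id]][, j]
      expect_equal(unname(col[chars[j]]), max(col))
    } else {
      expect_equal(chars[j], "-")
    }
  }
})

test_that("extract_ancestor resolves clades, singletons, and the root", {
  m <- aa_model("JTT")
  fam <- evolve_alignment(sample_yule_tree(6, 1, 19), 50, seed = 4)
  rec <- ancestral_reconstruction(fam$tree, fam$alignment, m)
  all_leaves <- fam$tree$tip.label
  expect_equal(extract_ancestor(rec, all_leaves)$node, "N1")
  expect_equal(extract_ancestor(rec, "t3")$node, "t3")
  # MRCA of a true subtree is the simulator's ancestor for that subtree
  kids <- fam$tree$edge[fam$tree$edge[, 1] ==
                          length(all_leaves) + 1L, 2]
  internal_kid <- kids[kids > length(all_leaves)][1]
  clade <- ape::extract.clade(fam$tree, internal_kid)$tip.label
  expect_equal(extract_ancestor(rec, clade)$node,
               hisatrace:::node_ids(fam$tree)[internal_kid])
  expect_error(extract_ancestor(rec, character(0)),
               class = "hisatrace_invalid_argument")
  expect_error(extract_ancestor(rec, "nope"), "nope")
})

test_that("reconstruction accuracy declines with divergence", {
  m <- aa_model("JTT")
  divs <- c(0.1, 0.6, 1.2, 2.0)
  acc <- vapply(divs, function(d) {
    ids <- vapply(1:3, function(s) {
      tr <- sample_yule_tree(8, 1, 40 + s)
      tr$edge.length <- tr$edge.length * d / max(ape::node.depth.edgelength(tr))
      fam <- evolve_alignment(tr, 200, m, indel_rate = 0, seed = 50 + s)
      rec <- ancestral_reconstruction(fam$tree, fam$alignment, m)
      ml <- rec$nodes$ml_sequence[rec$nodes$node == "N1"]
      percent_identity(ml, fam$true_ancestors[["N1"]])
    }, numeric(1))
    mean(ids)
  }, numeric(1))
  expect_lt(cor(divs, acc, method = "spearman"), 0)
})
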