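test_that("length filtering uses inclusive bounds", {
  seqs <- stats::setNames(
    vapply(c(229, 230, 260, 261), function(n) strrep("A", n), character(1)),
    c("a229", "a230", "a260", "a261"))
  kept <- filter_by_length(seqs, 230, 260)
  expect_identical(names(kept), c("a230", "a260"))
  expect_length(filter_by_length(character(0)), 0L)
  expect_error(filter_by_length(seqs, 300, 200),
               class = "hisatrace_invalid_argument")
})

test_that("representative collapsing is strict at the threshold", {
  # identical sequences merge
  dup <- c(s1 = strrep("MKTAYIAKQR", 10), s2 = strrep("MKTAYIAKQR", 10))
  coll <- collapse_representatives(dup, 95)
  expect_length(unique(coll$representative), 1L)

  # a pair at exactly 95.0% identity does NOT merge (strict >)
  base <- strsplit(strrep("MKTAYIAKQRGWDELSPNVH", 5), "")[[1]]  # 100 aa
  mut <- base
  mut[c(3, 23, 43, 63, 83)] <- c("W", "C", "P", "G", "M")  # 5 changes
  pair <- c(x = paste(base, collapse = ""), y = paste(mut, collapse = ""))
  expect_equal(hisatrace:::pid_shorter(pair[[1]], pair[[2]], blosum62()), 95)
  expect_length(unique(collapse_representatives(pair, 95)$representative), 2L)
  # but a 96%-identical pair does merge
  mut4 <- base
  mut4[c(3, 23, 43, 63)] <- c("W", "C", "P", "G")
  pair4 <- c(x = pair[[1]], y = paste(mut4, collapse = ""))
  expect_length(unique(collapse_representatives(pair4, 95)$representative), 1L)

  # collapsing at 100 with strict > merges only exact duplicates
  expect_length(unique(collapse_representatives(pair4, 100)$representative),
                2L)
  expect_length(unique(collapse_representatives(dup, 100)$representative), 1L)
})

test_that("two identity blocks collapse to two representatives and two components", {
  fam <- make_family_with_identity(8, 250,
                                   data.frame(size = c(4, 4),
                                              identity = c(0.98, 0.98)),
                                   seed = 11)
  coll <- collapse_representatives(fam, 95)
  expect_length(unique(coll$representative), 2L)
  net <- build_ssn(fam, min_len = 1, max_len = 1000)
  cs <- components_and_stats(net)
  expect_equal(nrow(cs), 2L)
  expect_equal(sort(cs$n_members), c(4L, 4L))
})

test_that("edges obey Karlin-Altschul statistics", {
  set.seed(3)
  a <- paste(sample(aa_states(), 250, replace = TRUE), collapse = "")
  # identical 250-mers: E far below the cutoff
  e1 <- allbyall_edges(c(x = a, y = a))
  expect_equal(nrow(e1), 1L)
  expect_lt(e1$evalue, 1e-54)
  expect_equal(e1$pid, 100)

  # unrelated random pairs: no edges at the default cutoff
  set.seed(7)
  rnd <- stats::setNames(vapply(1:8, function(i) {
    paste(sample(aa_states(), 250, replace = TRUE), collapse = "")
  }, character(1)), paste0("r", 1:8))
  expect_equal(nrow(allbyall_edges(rnd)), 0L)

  # E-value is monotone decreasing in the raw score at fixed lengths
  lambda <- 0.267; K <- 0.041
  S <- seq(50, 500, by = 50)
  E <- 250 * 250 * 2^(-(lambda * S - log(K)) / log(2))
  expect_true(all(diff(E) < 0))
})

test_that("raising the E-value cutoff only adds edges", {
  fam <- make_family_with_identity(9, 240,
                                   data.frame(size = c(3, 3, 3),
                                              identity = c(0.9, 0.8, 0.7)),
                                   seed = 5)
  cutoffs <- c(1e-80, 1e-54, 1e-20, 1)
  edge_sets <- lapply(cutoffs, function(cut) {
    e <- allbyall_edges(fam, evalue_cutoff = cut)
    paste(e$from, e$to)
  })
  for (k in seq_len(length(cutoffs) - 1)) {
    expect_true(all(edge_sets[[k]] %in% edge_sets[[k + 1]]))
  }
})

test_that("component partition is invariant under input order", {
  fam <- make_family_with_identity(8, 200,
                                   data.frame(size = c(4, 4),
                                              identity = c(0.95, 0.95)),
                                   seed = 8)
  n1 <- build_ssn(fam, min_len = 1, max_len = 1000)
  n2 <- build_ssn(rev(fam), min_len = 1, max_len = 1000)
  part <- function(net) {
    g <- hisatrace:::ssn_graph(net)
    comp <- igraph::components(g)$membership
    unname(lapply(split(names(comp), comp), sort))
  }
  expect_setequal(part(n1), part(n2))
})

test_that("cluster identity statistics track the generating identity", {
  fam <- make_family_with_identity(8, 300,
                                   data.frame(size = 8, identity = 0.52),
                                   seed = 4)
  # collapse threshold high enough that nothing merges at 52% identity
  net <- build_ssn(fam, min_len = 1, max_len = 1000, evalue_cutoff = 1)
  cs <- components_and_stats(net)
  big <- cs[cs$n_nodes == max(cs$n_nodes), ]
  expect_equal(big$mean_pid[1], 52, tolerance = 5 / 52)
  # singleton components report NA identity
  iso <- build_ssn(c(one = strrep("MKT", 80)), min_len = 1, max_len = 1000)
  expect_true(is.na(components_and_stats(iso)$mean_pid[1]))
})

test_that("GraphML export round-trips through igraph", {
  fam <- make_family_with_identity(4, 150,
                                   data.frame(size = 4, identity = 0.9),
                                   seed = 2)
  net <- build_ssn(fam, min_len = 1, max_len = 1000, evalue_cutoff = 1)
  path <- tempfile(fileext = ".graphml")
  write_ssn_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
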