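# Bayesian sampling over topologies and branch lengths, split-frequency
# convergence diagnostics (maxdiff), effective sample size, and the
# majority-rule consensus tree with posterior supports.

# canonical nontrivial splits of one tree: each split is represented by the
# sorted leaf set of the side NOT containing the reference taxon
canonical_splits <- function(tree, ref = NULL) {
  taxa <- tree$tip.label
  if (is.null(ref)) ref <- sort(taxa)[1]
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- taxa[cl]
    if (ref %in% side) side <- setdiff(taxa, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = ","))
    }
  }
  unique(out)
}

#' Split frequencies in a tree sample
#'
#' @param trees List (or `multiPhylo`) of trees over the same leaves.
#' @param ref Reference taxon for split canonicalization (default: first
#'   label alphabetically).
#' @return Named numeric vector: frequency of every observed nontrivial
#'   split (leaf sets comma-separated, excluding the reference side).
#' @export
split_frequencies <- function(trees, ref = NULL) {
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (s in canonical_splits(tr, ref)) {
      assign(s, (if (exists(s, counts)) get(s, counts) else 0) + 1, counts)
    }
  }
  nm <- ls(counts)
  out <- vapply(nm, get, numeric(1), envir = counts) / length(trees)
  names(out) <- nm
  out
}

#' Maximum split-frequency discrepancy between chains
#'
#' Over all nontrivial splits observed in any chain, the maximum over chain
#' pairs of the absolute difference in post-burnin split frequency — the
#' standard discrepancy index for assessing MCMC convergence.
#'
#' @param run An `mcmc_run` (or a list of frequency vectors via
#'   [maxdiff_from_freqs()]).
#' @param burnin Number of leading samples to discard per chain (default:
#'   the run's stored burnin).
#' @return A number in `[0, 1]`.
#' @export
maxdiff <- function(run, burnin = NULL) {
  stopifnot(inherits(run, "mcmc_run"))
  if (length(run$chains) < 2L) stop_invalid("need >= 2 chains")
  if (is.null(burnin)) burnin <- run$burnin
  freqs <- lapply(run$chains, function(ch) {
    trees <- ch$trees[(burnin + 1L):length(ch$trees)]
    if (length(trees) == 0L) stop_invalid("no post-burnin samples")
    split_frequencies(trees, ref = run$ref)
  })
  maxdiff_from_freqs(freqs)
}

#' @rdname maxdiff
#' @param freqs List of named split-frequency vectors, one per chain.
#' @export
maxdiff_from_freqs <- function(freqs) {
  all_splits <- unique(unlist(lapply(freqs, names)))
  if (length(all_splits) == 0L) return(0)
  F <- vapply(freqs, function(f) {
    v <- rep(0, length(all_splits))
    v[match(names(f), all_splits)] <- f
    v
  }, numeric(length(all_splits)))
  F <- matrix(F, nrow = length(all_splits))
  md <- 0
  for (i in seq_len(ncol(F) - 1)) {
    for (j in (i + 1):ncol(F)) {
      md <- max(md, max(abs(F[, i] - F[, j])))
    }
  }
  md
}

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule (pairs of consecutive autocorrelations are
#' summed until a pair goes non-positive). Capped at `N`.
#'
#' @param trace Numeric vector, length >= 10.
#' @return Effective sample size in `[1, length(trace)]`.
#' @export
ess <- function(trace) {
  N <- length(trace)
  if (N < 10L) stop_invalid("trace must have length >= 10")
  if (var(trace) == 0) {
    warn("constant trace: effective size reported as N")
    return(N)
  }
  lag_max <- min(N - 1L, max(100L, floor(10 * sqrt(N))))
  rho <- as.vector(stats::acf(trace, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)  # rho[1] = lag 0
  # Geyer initial positive sequence on Gamma_m = rho_{2m} + rho_{2m+1}
  gam <- numeric(0)
  m <- 0
  repeat {
    i1 <- 2 * m + 1L        # lag 2m
    i2 <- 2 * m + 2L        # lag 2m+1
    if (i1 > length(rho)) break
    g <- rho[i1] + (if (i2 <= length(rho)) rho[i2] else 0)
    if (g <= 0) break
    gam <- c(gam, g)
    m <- m + 1
  }
  denom <- max(2 * sum(gam) - 1, 1)
  min(N, max(1, N / denom))
}

#' Metropolis-Hastings sampling of trees
#'
#' Samples tree topology and branch lengths by Metropolis-Hastings: random
#' NNI moves on the topology (uniform prior), multiplier proposals on a
#' random branch length (exponential(10) prior), and an optional sliding
#' window on the gamma shape when the model has one. Chains are independent
#' given their seeds (chain `c` uses `seed + c - 1`).
#'
#' @param aln An `aa_alignment`.
#' @param model A `ctmc_model`.
#' @param n_chains Number of chains (>= 2 for diagnostics).
#' @param n_samples Samples per chain.
#' @param burnin_frac Fraction of samples discarded as burnin by the
#'   diagnostics (default 0.1).
#' @param seed Integer master seed.
#' @param start Optional starting tree (default: NJ on ML distances).
#' @return An `mcmc_run`: chains (each with `trees`, `loglik`,
#'   `tree_length`, `alpha`), `n_samples`, `burnin`, `ref`.
#' @export
mcmc_sample <- function(aln, model = aa_model("JTT"), n_chains = 4L,
                        n_samples = 2000L, burnin_frac = 0.1, seed = 1L,
                        start = NULL) {
  if (n_chains < 1L) stop_invalid("need >= 1 chain")
  if (is.null(start)) {
    start <- nj_tree(ml_distances(aln, model))
    start$edge.length[start$edge.length <= 0] <- 1e-4
  }
  chains <- lapply(seq_len(n_chains), function(c) {
    .mcmc_chain(aln, model, n_samples, start, seed + c - 1L)
  })
  structure(list(chains = chains, n_samples = n_samples,
                 burnin = floor(burnin_frac * n_samples),
                 ref = sort(start$tip.label)[1]),
            class = "mcmc_run")
}

.mcmc_chain <- function(aln, model, n_samples, start, seed) {
  prior_rate <- 10
  logpost <- function(tr, ll) ll + sum(stats::dexp(tr$edge.length, prior_rate,
                                                   log = TRUE))
  with_seed(seed, {
    tree <- start
    ll <- tree_log_likelihood(tree, aln, model)
    lp <- logpost(tree, ll)
    trees <- vector("list", n_samples)
    lls <- numeric(n_samples)
    tlen <- numeric(n_samples)
    alph <- rep(NA_real_, n_samples)
    has_alpha <- !is.null(model$alpha)
    for (s in seq_len(n_samples)) {
      u <- runif(1)
      if (u < 0.4 && length(tree$tip.label) > 3L) {
        prop <- phangorn::rNNI(tree, 1)
        log_hastings <- 0
      } else if (has_alpha && u > 0.9) {
        prop <- tree
        new_alpha <- abs(model$alpha + runif(1, -0.5, 0.5))  # reflect at 0
        model2 <- model
        model2$alpha <- max(new_alpha, 1e-3)
        ll2 <- tree_log_likelihood(prop, aln, model2)
        lp2 <- logpost(prop, ll2)
        if (log(runif(1)) < lp2 - lp) {
          model <- model2
          ll <- ll2
          lp <- lp2
        }
        trees[[s]] <- tree
        lls[s] <- ll
        tlen[s] <- sum(tree$edge.length)
        alph[s] <- model$alpha
        next
      } else {
        prop <- tree
        e <- sample.int(length(prop$edge.length), 1L)
        m <- exp(runif(1, -0.5, 0.5))
        prop$edge.length[e] <- prop$edge.length[e] * m
        log_hastings <- log(m)
      }
      ll2 <- tree_log_likelihood(prop, aln, model)
      lp2 <- logpost(prop, ll2)
      if (log(runif(1)) < lp2 - lp + log_hastings) {
        tree <- prop
        ll <- ll2
        lp <- lp2
      }
      trees[[s]] <- tree
      lls[s] <- ll
      tlen[s] <- sum(tree$edge.length)
      if (has_alpha) alph[s] <- model$alpha
    }
    list(trees = trees, loglik = lls, tree_length = tlen, alpha = alph)
  })
}

#' @export
print.mcmc_run <- function(x, ...) {
  cat(sprintf("<mcmc_run> %d chains x %d samples (burnin %d)\n",
              length(x$chains), x$n_samples, x$burnin))
  invisible(x)
}

#' Tidy MCMC traces
#' @param x An `mcmc_run`.
#' @param ... Unused.
#' @return Tibble: chain, sample, loglik, tree_length, alpha.
#' @export
tidy.mcmc_run <- function(x, ...) {
  purrr::map_dfr(seq_along(x$chains), function(c) {
    ch <- x$chains[[c]]
    tibble(chain = c, sample = seq_along(ch$loglik),
           loglik = ch$loglik, tree_length = ch$tree_length,
           alpha = ch$alpha)
  })
}

#' Convergence summary of an MCMC run
#' @param x An `mcmc_run`.
#' @param ... Unused.
#' @return One-row tibble: maxdiff, min_ess_loglik, min_ess_tree_length.
#' @export
glance.mcmc_run <- function(x, ...) {
  post <- function(v, ch) v[(x$burnin + 1):length(v)]
  tibble(
    maxdiff = if (length(x$chains) >= 2L) maxdiff(x) else NA_real_,
    min_ess_loglik = min(vapply(x$chains, function(ch)
      ess(post(ch$loglik)), numeric(1))),
    min_ess_tree_length = min(vapply(x$chains, function(ch)
      ess(post(ch$tree_length)), numeric(1))))
}

#' Majority-rule consensus tree with split supports
#'
#' Pools the post-burnin trees of all chains, keeps every nontrivial split
#' with pooled frequency > 0.5, and greedily extends the set with the most
#' frequent compatible remaining splits. Supports are pooled frequencies;
#' they are written on the internal node labels of the returned tree.
#'
#' @param run An `mcmc_run`.
#' @param burnin Samples discarded per chain (default: the run's burnin).
#' @return A `split_support_tree`: list with `tree` (`phylo`, node labels =
#'   supports) and `splits` (tibble: split, support).
#' @export
consensus_with_support <- function(run, burnin = NULL) {
  stopifnot(inherits(run, "mcmc_run"))
  if (is.null(burnin)) burnin <- run$burnin
  if (burnin >= run$n_samples) stop_invalid("burnin must be < n_samples")
  pooled <- unlist(lapply(run$chains, function(ch) {
    ch$trees[(burnin + 1L):length(ch$trees)]
  }), recursive = FALSE)
  taxa <- sort(pooled[[1]]$tip.label)
  freqs <- split_frequencies(pooled, ref = taxa[1])
  ord <- order(-freqs, names(freqs))
  freqs <- freqs[ord]
  sets <- strsplit(names(freqs), ",", fixed = TRUE)
  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0L || i == length(a) || i == length(b)
  }
  # splits above 0.5 are mutually compatible by counting; the greedy
  # extension adds the most frequent compatible remaining splits
  kept <- integer(0)
  for (k in seq_along(sets)) {
    if (all(vapply(kept, function(j) compatible(sets[[k]], sets[[j]]),
                   logical(1)))) {
      kept <- c(kept, k)
    }
  }
  clades <- sets[kept]
  supports <- unname(freqs[kept])
  tree <- .tree_from_clades(taxa, clades, supports)
  structure(list(tree = tree,
                 splits = tibble(split = names(freqs)[kept],
                                 support = supports)),
            class = "split_support_tree")
}

# Build an unrooted consensus topology from a laminar family of clades
# (all excluding the reference taxon taxa[1]); supports become node labels.
.tree_from_clades <- function(taxa, clades, supports) {
  ref <- taxa[1]
  universe <- setdiff(taxa, ref)
  ord <- order(-lengths(clades))
  clades <- clades[ord]
  supports <- supports[ord]
  # content of the ring of children for a member set, descending into the
  # laminar family of clades
  ring <- function(members, inside) {
    tops <- inside[vapply(inside, function(i) {
      !any(vapply(inside, function(j) {
        j != i && length(clades[[i]]) < length(clades[[j]]) &&
          all(clades[[i]] %in% clades[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- unique(unlist(clades[tops]))
    parts <- c(
      vapply(tops, function(i) {
        sub <- inside[vapply(inside, function(j) {
          j != i && length(clades[[j]]) < length(clades[[i]]) &&
            all(clades[[j]] %in% clades[[i]])
        }, logical(1))]
        paste0("(", ring(clades[[i]], sub), ")", sprintf("%.4g", supports[i]))
      }, character(1)),
      sort(setdiff(members, covered)))
    paste(parts, collapse = ",")
  }
  nwk <- paste0("(", ref, ",", ring(universe, seq_along(clades)), ");")
  ape::read.tree(text = nwk)
}

#' @export
print.split_support_tree <- function(x, ...) {
  cat("<split_support_tree>\n")
  print(x$splits)
  invisible(x)
}
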