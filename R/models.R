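#' Amino-acid alphabet
#'
#' One-letter codes in the canonical order used throughout the package for
#' state indexing (the same order the empirical replacement matrices are
#' published in).
#'
#' @return Character vector of the 20 amino-acid one-letter codes.
#' @export
aa_states <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Characters treated as fully missing in likelihood computations.
.missing_chars <- c("-", "X", "B", "Z", "?", ".", "*")

#' Build a reversible continuous-time substitution model
#'
#' Constructs a general time-reversible CTMC over an arbitrary state space
#' from symmetric exchangeabilities and equilibrium frequencies. The rate
#' matrix is `Q = S diag(pi)` with the diagonal set so rows sum to zero,
#' normalized so that the expected number of substitutions per unit branch
#' length is one (`-sum(pi_i Q_ii) = 1`). The spectral decomposition of the
#' symmetrized matrix is cached so transition probabilities
#' `P(t) = exp(Qt)` are cheap for any `t`.
#'
#' @param rates Symmetric exchangeability matrix (or lower-triangle vector in
#'   column-major order) over `length(freqs)` states.
#' @param freqs Equilibrium frequencies, non-negative, summing to 1.
#' @param states Character vector of state labels.
#' @param name Model name for printing.
#' @param alpha Optional shape of discrete-gamma rate heterogeneity.
#' @param n_categories Number of equal-weight gamma categories (default 4).
#' @return An object of class `ctmc_model`.
#' @export
ctmc_model <- function(rates, freqs, states, name = "custom",
                       alpha = NULL, n_categories = 4L) {
  k <- length(states)
  if (length(freqs) != k) stop_invalid("`freqs` length must match `states`")
  if (any(freqs < 0)) stop_invalid("`freqs` must be non-negative")
  freqs <- freqs / sum(freqs)
  if (is.matrix(rates)) {
    S <- rates
  } else {
    S <- matrix(0, k, k)
    S[lower.tri(S)] <- rates
    S <- S + t(S)
  }
  if (nrow(S) != k) stop_invalid("`rates` dimension must match `states`")
  diag(S) <- 0
  Q <- S %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  # symmetrize: B = D^{1/2} Q D^{-1/2} has real eigen-decomposition
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  if (!is.null(alpha)) {
    check_scalar_number(alpha, "alpha", positive = TRUE)
    n_categories <- as.integer(n_categories)
  }
  structure(
    list(name = name, states = states, freqs = freqs, Q = Q,
         evec = diag(1 / d) %*% eig$vectors,
         ivec = t(eig$vectors) %*% diag(d),
         evals = eig$values,
         alpha = alpha, n_categories = n_categories),
    class = "ctmc_model")
}

#' Empirical amino-acid substitution models
#'
#' The JTT (default) and WAG empirical amino-acid replacement models, with
#' optional discrete-gamma rate heterogeneity (equal-weight categories, rates
#' set to category means).
#'
#' @param name `"JTT"` or `"WAG"`.
#' @param alpha Optional gamma shape; `NULL` for rate homogeneity.
#' @param n_categories Number of gamma categories.
#' @param freqs Optional replacement equilibrium frequencies (e.g. observed
#'   "+F" frequencies); defaults to the model's published frequencies.
#' @return A `ctmc_model` over the 20 amino acids.
#' @export
aa_model <- function(name = c("JTT", "WAG"), alpha = NULL, n_categories = 4L,
                     freqs = NULL) {
  name <- match.arg(name)
  rates <- switch(name, JTT = .jtt_rates, WAG = .wag_rates)
  f <- if (is.null(freqs)) switch(name, JTT = .jtt_freqs, WAG = .wag_freqs)
       else freqs
  ctmc_model(rates, f, aa_states(), name = name,
             alpha = alpha, n_categories = n_categories)
}

#' Two-state presence/absence model for indel reconstruction
#'
#' Reversible two-state (absent/present) CTMC with equal equilibrium
#' frequencies and a single gain/loss rate, used to reconstruct ancestral
#' residue presence from gap patterns.
#'
#' @param gain_loss_rate Rate of the gain/loss process on the branch-length
#'   scale of the tree.
#' @return A `ctmc_model` over states `"0"` (absent) and `"1"` (present).
#' @export
presence_model <- function(gain_loss_rate = 1) {
  check_scalar_number(gain_loss_rate, "gain_loss_rate", positive = TRUE)
  m <- ctmc_model(matrix(c(0, 1, 1, 0), 2, 2), c(0.5, 0.5), c("0", "1"),
                  name = "presence")
  # undo the unit-rate normalization: Q is +-1 off-diagonal after normalizing,
  # rescale so the off-diagonal rate equals gain_loss_rate
  m$evals <- m$evals * gain_loss_rate
  m$Q <- m$Q * gain_loss_rate
  m
}

#' @export
print.ctmc_model <- function(x, ...) {
  cat(sprintf("<ctmc_model> %s: %d states", x$name, length(x$states)))
  if (!is.null(x$alpha)) {
    cat(sprintf(", gamma(alpha=%.3g, %d categories)", x$alpha,
                x$n_categories))
  }
  cat("\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Qt)` via the cached spectral decomposition. Rows index the
#' starting state.
#'
#' @param model A `ctmc_model`.
#' @param t Branch length (expected substitutions per site), `>= 0`.
#' @param rate Optional rate multiplier (gamma category rate).
#' @return A stochastic matrix of transition probabilities.
#' @export
transition_prob <- function(model, t, rate = 1) {
  check_scalar_number(t, "t", nonneg = TRUE)
  P <- model$evec %*% (exp(model$evals * t * rate) * model$ivec)
  # clamp tiny negatives from round-off
  P[P < 0] <- 0
  P
}

#' Discrete-gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a Gamma(alpha, alpha)
#' distribution (mean 1), the standard discretization for among-site rate
#' heterogeneity.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` category rates with mean 1.
#' @export
gamma_rates <- function(alpha, k = 4L) {
  check_scalar_number(alpha, "alpha", positive = TRUE)
  k <- as.integer(k)
  if (k < 1L) stop_invalid("`k` must be >= 1")
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  # category mean via incomplete-gamma identity:
  # E[X | a<X<b] * P = pgamma(b, a+1) - pgamma(a, a+1)  (rate = alpha -> mean 1)
  pg <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  bounds <- c(0, pg, 1)
  k * diff(bounds)
}

model_rates <- function(model) {
  if (is.null(model$alpha)) 1 else gamma_rates(model$alpha, model$n_categories)
}
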