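# Michaelis-Menten kinetics: progress-curve simulation, the integrated rate
# equation (Lambert W form), initial-rate and global progress-curve fitting
# (optional competitive product inhibition), catalytic efficiencies, and
# rank concordance with in vivo complementation times.

#' Catalytic efficiency kcat/KM
#'
#' @param kcat Turnover number in 1/s.
#' @param KM Michaelis constant in uM.
#' @param digits Significant figures for reporting (default 2, the usual
#'   table convention); `NULL` for full precision.
#' @return Efficiency in 1/(M*s).
#' @export
catalytic_efficiency <- function(kcat, KM, digits = 2) {
  if (any(kcat <= 0, na.rm = TRUE) || any(KM <= 0, na.rm = TRUE)) {
    stop_invalid("`kcat` and `KM` must be > 0")
  }
  eff <- kcat / (KM * 1e-6)
  if (!is.null(digits)) eff <- signif(eff, digits)
  eff
}

# principal Lambert W taken on the log scale: solves w + log(w) = y, i.e.
# W(exp(y)), by safeguarded Newton on the (strictly increasing) log form.
# Working on y rather than exp(y) avoids overflow for large substrate/KM
# ratios.
lambertW_log <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi)) return(if (yi < 0) 0 else Inf)
    # init: W ~ exp(y) for small arguments, y - log(y) for large ones
    w <- if (yi > 1) yi - log(yi) else exp(yi)
    if (w <= 0) w <- .Machine$double.xmin
    for (i in 1:100) {
      delta <- (w + log(w) - yi) * w / (w + 1)
      wn <- w - delta
      while (wn <= 0) {          # safeguard: stay in the positive domain
        delta <- delta / 2
        wn <- w - delta
      }
      w <- wn
      if (abs(delta) <= 1e-13 * max(w, 1e-300)) break
    }
    w
  }, numeric(1))
}

#' Integrated Michaelis-Menten progress curve
#'
#' Closed-form product concentration
#' `P(t) = S0 - KM * W((S0/KM) * exp((S0 - kcat*E0*t)/KM))`
#' with `W` the principal branch of the Lambert function, evaluated through
#' a log-argument form so large `S0/KM` ratios do not overflow.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param kcat Turnover number (1/s).
#' @param KM Michaelis constant (uM).
#' @param E0 Enzyme concentration (uM).
#' @param S0 Initial substrate concentration (uM).
#' @return Product concentration(s) in uM.
#' @export
integrated_mm_product <- function(t, kcat, KM, E0, S0) {
  for (nm in c("kcat", "KM", "E0", "S0")) {
    check_scalar_number(get(nm), nm, positive = TRUE)
  }
  y <- log(S0 / KM) + (S0 - kcat * E0 * t) / KM
  S0 - KM * lambertW_log(y)
}

mm_rate <- function(P, kcat, KM, E0, S0, Ki = NULL,
                    inhibition = "competitive") {
  S <- pmax(S0 - P, 0)
  if (is.null(Ki)) {
    kcat * E0 * S / (KM + S)
  } else if (inhibition == "competitive") {
    kcat * E0 * S / (KM * (1 + P / Ki) + S)
  } else {  # uncompetitive: inhibitor term on the substrate-bound form
    kcat * E0 * S / (KM + S * (1 + P / Ki))
  }
}

ode_progress <- function(times, kcat, KM, E0, S0, Ki = NULL,
                         inhibition = "competitive") {
  sol <- deSolve::ode(
    y = c(P = 0), times = times,
    func = function(t, y, parms) {
      list(mm_rate(y[["P"]], kcat, KM, E0, S0, Ki, inhibition))
    }, parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-9)
  out <- as.numeric(sol[, "P"])
  if (length(out) != length(times) || any(!is.finite(out))) {
    stop("progress-curve integration failed")
  }
  out
}

#' Simulate noisy Michaelis-Menten progress curves
#'
#' Integrates `dP/dt = kcat*E0*(S0-P) / (KM*(1+P/Ki) + (S0-P))` (plain
#' Michaelis-Menten when `Ki` is absent) from `P(0) = 0` and adds i.i.d.
#' Gaussian noise to the signal, one curve per initial substrate
#' concentration.
#'
#' @param kcat Turnover number (1/s).
#' @param KM Michaelis constant (uM).
#' @param E0 Enzyme concentration (uM).
#' @param S0_list Initial substrate concentrations (uM), all > 0.
#' @param Ki Optional product-inhibition constant (uM).
#' @param noise_sd Gaussian noise standard deviation (signal units, uM).
#' @param dt Sampling interval (s).
#' @param t_end End time (s).
#' @param seed Integer seed.
#' @return Tibble: `curve_id`, `S0_uM`, `E0_uM`, `t_s`, `P_uM`.
#' @export
simulate_progress_curves <- function(kcat, KM, E0, S0_list, Ki = NULL,
                                     noise_sd = 0, dt = 1, t_end = 600,
                                     seed = 1L) {
  if (any(S0_list <= 0)) stop_invalid("all S0 must be > 0")
  check_scalar_number(dt, "dt", positive = TRUE)
  check_scalar_number(E0, "E0", positive = TRUE)
  times <- seq(0, t_end, by = dt)
  with_seed(seed, {
    purrr::map_dfr(seq_along(S0_list), function(i) {
      S0 <- S0_list[i]
      P <- if (is.null(Ki)) {
        integrated_mm_product(times, kcat, KM, E0, S0)
      } else {
        ode_progress(times, kcat, KM, E0, S0, Ki)
      }
      if (noise_sd > 0) {
        P <- P + rnorm(length(P), 0, noise_sd)
        P[1] <- 0
      }
      tibble(curve_id = paste0("S0_", format(S0)), S0_uM = S0, E0_uM = E0,
             t_s = times, P_uM = P)
    })
  })
}

#' Fit Michaelis-Menten parameters from initial rates
#'
#' Nonlinear least squares of `v = kcat * E0 * S / (KM + S)` against initial
#' rates. When saturation is not reached (all substrate concentrations below
#' half the apparent KM), only the second-order rate constant kcat/KM is
#' identifiable: the fit falls back to the linear regime
#' (`v = (kcat/KM) * E0 * S`) and flags the result.
#'
#' @param rates Tibble with columns `S0_uM` and `v_uM_s`.
#' @param E0 Enzyme concentration (uM).
#' @return An `mm_fit`: list with `params` (tibble: term, estimate,
#'   std.error), `kcat_over_KM` (1/(M*s)), `linear_regime` flag, `E0`.
#' @export
fit_initial_rates <- function(rates, E0) {
  if (nrow(rates) < 2L) stop_invalid("need >= 2 rate measurements")
  check_scalar_number(E0, "E0", positive = TRUE)
  S <- rates$S0_uM
  v <- rates$v_uM_s
  kcat0 <- max(v) / E0
  KM0 <- max(stats::median(S), 1e-3)
  fit <- tryCatch(
    stats::nls(v ~ kcat * E0 * S / (KM + S),
               start = list(kcat = kcat0 * 1.5, KM = KM0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE),
               lower = c(kcat = 1e-12, KM = 1e-9), algorithm = "port"),
    error = function(e) NULL)
  linear <- is.null(fit) || max(S) < stats::coef(fit)[["KM"]] / 2
  if (linear) {
    lf <- stats::lm(v ~ 0 + S)
    slope <- stats::coef(lf)[[1]]
    eff <- slope / E0 / 1e-6
    params <- tibble(term = "kcat_over_KM", estimate = eff,
                     std.error = summary(lf)$coefficients[1, 2] / E0 / 1e-6)
    out <- list(params = params, kcat_over_KM = eff, linear_regime = TRUE,
                E0 = E0, fit = lf)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, 2],
                   error = function(e) c(kcat = NA, KM = NA))
    params <- tibble(term = c("kcat", "KM"),
                     estimate = c(cf[["kcat"]], cf[["KM"]]),
                     std.error = c(se[["kcat"]], se[["KM"]]))
    out <- list(params = params,
                kcat_over_KM = catalytic_efficiency(cf[["kcat"]], cf[["KM"]],
                                                    digits = NULL),
                linear_regime = FALSE, E0 = E0, fit = fit)
  }
  structure(out, class = "mm_fit")
}

#' Fit kinetic parameters from full progress curves
#'
#' Single global least-squares fit across all curves: the plain model uses
#' the closed-form integrated Michaelis-Menten solution, the
#' product-inhibition model integrates the rate law numerically (competitive
#' inhibition by default: the inhibitor term scales KM). Parameters are
#' fitted on the log scale from multiple starting points (5 log-spaced KM
#' guesses); standard errors come from the Jacobian at the optimum. A fit
#' whose Jacobian is ill-conditioned is flagged, not silently returned.
#'
#' @param curves Tibble from [simulate_progress_curves()] (columns
#'   `curve_id`, `S0_uM`, `E0_uM`, `t_s`, `P_uM`).
#' @param model `"plain"` or `"product_inhibition"`.
#' @param inhibition `"competitive"` (default) or `"uncompetitive"`.
#' @param n_starts Number of multi-start initializations.
#' @return An `mm_fit` with params kcat, KM (and Ki), `kcat_over_KM`,
#'   `identifiable` flag, `residuals` tibble.
#' @export
fit_progress_curves <- function(curves, model = c("plain",
                                                  "product_inhibition"),
                                inhibition = c("competitive",
                                               "uncompetitive"),
                                n_starts = 5L) {
  model <- match.arg(model)
  inhibition <- match.arg(inhibition)
  if (nrow(curves) == 0L) stop_invalid("no curves supplied")
  split_curves <- split(curves, curves$curve_id)
  predict_all <- function(kcat, KM, Ki) {
    unlist(lapply(split_curves, function(cc) {
      if (model == "plain") {
        integrated_mm_product(cc$t_s, kcat, KM, cc$E0_uM[1], cc$S0_uM[1])
      } else {
        ode_progress(cc$t_s, kcat, KM, cc$E0_uM[1], cc$S0_uM[1], Ki,
                     inhibition)
      }
    }), use.names = FALSE)
  }
  obs <- unlist(lapply(split_curves, function(cc) cc$P_uM),
                use.names = FALSE)
  n_par <- if (model == "plain") 2L else 3L
  resid_fn <- function(logpar) {
    # clamp to a broad physical range so the integrator never sees
    # pathologically stiff parameter combinations during line searches
    p <- exp(pmin(pmax(logpar, log(1e-8)), log(1e8)))
    pr <- tryCatch(
      suppressWarnings(predict_all(p[1], p[2],
                                   if (n_par == 3L) p[3] else NULL)),
      error = function(e) rep(1e6, length(obs)))
    pr - obs
  }
  # crude scale guesses from the data
  S0max <- max(curves$S0_uM)
  E0 <- curves$E0_uM[1]
  vmax0 <- max(diff(split_curves[[1]]$P_uM) /
                 diff(split_curves[[1]]$t_s), 1e-6)
  kcat0 <- vmax0 / E0
  KM_grid <- S0max * 10^seq(-2, 2, length.out = n_starts)
  best <- NULL
  for (KM0 in KM_grid) {
    start <- log(c(kcat0, KM0, if (n_par == 3L) KM0 else NULL))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop_invalid("progress-curve fit failed to converge")
  p <- exp(best$par)
  terms <- c("kcat", "KM", if (n_par == 3L) "Ki")
  # delta-method SEs from the log-scale Jacobian
  J <- best$hessian
  dof <- max(length(obs) - n_par, 1)
  sigma2 <- best$deviance / dof
  cv <- tryCatch(sigma2 * solve(J), error = function(e) NULL)
  se_log <- if (is.null(cv)) rep(NA_real_, n_par) else sqrt(pmax(diag(cv), 0))
  kappa <- tryCatch(kappa(J, exact = TRUE), error = function(e) Inf)
  fitted_vals <- predict_all(p[1], p[2], if (n_par == 3L) p[3] else NULL)
  structure(list(
    params = tibble(term = terms, estimate = unname(p),
                    std.error = unname(p * se_log)),
    kcat_over_KM = catalytic_efficiency(p[1], p[2], digits = NULL),
    model = model, inhibition = inhibition,
    identifiable = is.finite(kappa) && kappa < 1e8,
    condition_number = kappa,
    deviance = best$deviance, E0 = E0,
    residuals = dplyr::mutate(curves, fitted = fitted_vals,
                              resid = .data$P_uM - fitted_vals)),
    class = c("progress_fit", "mm_fit"))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit>", if (isTRUE(x$linear_regime)) "(linear regime)" else "",
      "\n")
  print(x$params)
  cat(sprintf("kcat/KM = %.3g 1/(M s)\n", x$kcat_over_KM))
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) x$params

#' @export
glance.mm_fit <- function(x, ...) {
  get_par <- function(term) {
    i <- match(term, x$params$term)
    if (is.na(i)) NA_real_ else x$params$estimate[i]
  }
  tibble(kcat = get_par("kcat"), KM = get_par("KM"), Ki = get_par("Ki"),
         kcat_over_KM = x$kcat_over_KM,
         linear_regime = isTRUE(x$linear_regime),
         identifiable = if (is.null(x$identifiable)) TRUE
                        else x$identifiable,
         deviance = if (is.null(x$deviance)) NA_real_ else x$deviance)
}

#' Wald-Wolfowitz runs test on progress-curve residual signs
#'
#' Systematic misfit (e.g. fitting a plain model to strongly inhibited
#' data) shows up as long runs of same-sign residuals in time; this tests
#' the residual sign sequence of each curve for non-randomness and returns
#' the per-curve and combined (Fisher) p-values.
#'
#' @param fit A `progress_fit`.
#' @return List with `p_per_curve` (named) and `p_combined`.
#' @export
residual_runs_test <- function(fit) {
  stopifnot(inherits(fit, "progress_fit"))
  ps <- vapply(split(fit$residuals, fit$residuals$curve_id), function(cc) {
    s <- sign(cc$resid)
    s <- s[s != 0]
    n1 <- sum(s > 0); n2 <- sum(s < 0)
    if (n1 == 0 || n2 == 0) return(0)  # all one sign: maximal misfit
    runs <- 1 + sum(diff(s) != 0)
    mu <- 1 + 2 * n1 * n2 / (n1 + n2)
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
      ((n1 + n2)^2 * (n1 + n2 - 1))
    stats::pnorm((runs - mu) / sqrt(v))  # one-sided: too few runs
  }, numeric(1))
  chi <- -2 * sum(log(pmax(ps, 1e-300)))
  list(p_per_curve = ps,
       p_combined = stats::pchisq(chi, df = 2 * length(ps),
                                  lower.tail = FALSE))
}

#' Rank concordance between catalytic efficiencies and complementation times
#'
#' Spearman rank correlation (midranks for ties) between in vitro catalytic
#' efficiencies and in vivo complementation times of the same enzymes.
#'
#' @param efficiencies Named numeric vector, 1/(M*s).
#' @param times Named numeric vector, hours.
#' @return Spearman rho in `[-1, 1]`.
#' @export
rank_concordance <- function(efficiencies, times) {
  shared <- intersect(names(efficiencies), names(times))
  if (length(shared) < 3L) stop_invalid("need >= 3 shared enzymes")
  cor(efficiencies[shared], times[shared], method = "spearman")
}
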