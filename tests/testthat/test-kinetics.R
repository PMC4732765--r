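test_that("catalytic efficiency reproduces published table values", {
  expect_equal(catalytic_efficiency(0.9, 28), 3.2e4)
  expect_equal(catalytic_efficiency(1.0, 5.6), 1.8e5)
  expect_equal(catalytic_efficiency(1.0, 1e6), 1.0)  # KM of 1 M sanity
  # efficiency is monotone decreasing in KM at fixed kcat
  eff <- catalytic_efficiency(1, c(1, 10, 100, 1000), digits = NULL)
  expect_true(all(diff(eff) < 0))
  expect_error(catalytic_efficiency(-1, 2),
               class = "hisatrace_invalid_argument")
  # full-precision value within 0.5% of the rounded report
  expect_equal(catalytic_efficiency(0.9, 28, digits = NULL),
               catalytic_efficiency(0.9, 28), tolerance = 0.005)
})

test_that("the Lambert-W closed form agrees with the ODE everywhere", {
  t <- seq(0, 3000, by = 10)
  for (par in list(c(0.9, 28, 0.1, 50),     # scPriA-like
                   c(7.8, 17, 0.01, 200),   # seHisA-like
                   c(0.05, 0.5, 0.2, 5))) { # ancestor-like
    Pc <- integrated_mm_product(t, par[1], par[2], par[3], par[4])
    Po <- hisatrace:::ode_progress(t, par[1], par[2], par[3], par[4])
    expect_lt(max(abs(Pc - Po) / pmax(Po, 1e-6 * par[4])), 1e-3)
  }
  expect_equal(integrated_mm_product(0, 0.9, 28, 0.1, 50), 0,
               tolerance = 1e-10)
  expect_equal(integrated_mm_product(1e7, 0.9, 28, 0.1, 50), 50,
               tolerance = 1e-6)
})

test_that("simulated progress curves exhaust substrate and obey the first-order limit", {
  cur <- simulate_progress_curves(0.9, 28, 0.5, 40, noise_sd = 0, dt = 10,
                                  t_end = 20000, seed = 1)
  expect_lt(abs(max(cur$P_uM) - 40) / 40, 0.001)
  expect_equal(cur$P_uM[cur$t_s == 0], 0)
  # S0 << KM: initial slope ~ (kcat/KM) * E0 * S0
  lowS <- simulate_progress_curves(0.9, 28, 0.1, 0.05, noise_sd = 0,
                                   dt = 0.01, t_end = 0.2, seed = 1)
  slope <- (lowS$P_uM[2] - lowS$P_uM[1]) / (lowS$t_s[2] - lowS$t_s[1])
  expect_equal(slope, (0.9 / 28) * 0.1 * 0.05, tolerance = 0.02)
  expect_error(simulate_progress_curves(1, 1, 1, c(10, -5)),
               class = "hisatrace_invalid_argument")
})

test_that("noise-free simulated curves match the closed form everywhere", {
  # scPriA-like constants: simulator output vs closed form within 0.1%
  cur <- simulate_progress_curves(0.9, 28, 0.1, c(20, 60), noise_sd = 0,
                                  dt = 5, t_end = 4000, seed = 2)
  for (S0 in c(20, 60)) {
    cc <- cur[cur$S0_uM == S0, ]
    expected <- integrated_mm_product(cc$t_s, 0.9, 28, 0.1, S0)
    expect_lt(max(abs(cc$P_uM - expected) / pmax(expected, 1e-3)), 1e-3)
  }
})

test_that("initial-rate fits recover parameters and flag the linear regime", {
  E0 <- 0.01
  S <- c(2, 5, 10, 20, 40, 80, 160, 320)
  v <- 7.8 * E0 * S / (17 + S)  # seHisA-like constants
  fit <- fit_initial_rates(tibble::tibble(S0_uM = S, v_uM_s = v), E0)
  expect_false(fit$linear_regime)
  expect_equal(fit$params$estimate[fit$params$term == "kcat"], 7.8,
               tolerance = 0.01)
  expect_equal(fit$params$estimate[fit$params$term == "KM"], 17,
               tolerance = 0.01)

  # all S0 << KM: only kcat/KM identifiable, within 5%
  S2 <- c(0.1, 0.2, 0.4, 0.8)
  v2 <- 7.8 * E0 * S2 / (17 + S2)
  fit2 <- fit_initial_rates(tibble::tibble(S0_uM = S2, v_uM_s = v2), E0)
  expect_true(fit2$linear_regime)
  expect_equal(fit2$kcat_over_KM, 7.8 / 17e-6, tolerance = 0.05)
  expect_error(fit_initial_rates(tibble::tibble(S0_uM = 1, v_uM_s = 1), 1),
               class = "hisatrace_invalid_argument")
})

test_that("global progress-curve fits recover parameters from clean curves", {
  cur <- simulate_progress_curves(0.9, 28, 0.1, c(10, 20, 40, 80, 160),
                                  noise_sd = 0, dt = 10, t_end = 3000,
                                  seed = 1)
  fit <- fit_progress_curves(cur, "plain")
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["kcat"]), 0.9, tolerance = 0.005)
  expect_equal(unname(est["KM"]), 28, tolerance = 0.005)
  expect_true(fit$identifiable)
  g <- glance(fit)
  expect_equal(g$kcat_over_KM, 0.9 / 28e-6, tolerance = 0.005)
})

test_that("product inhibition is recoverable and misfit is detectable", {
  cur <- simulate_progress_curves(0.9, 28, 0.2, c(20, 40, 80), Ki = 20,
                                  noise_sd = 0.05, dt = 20, t_end = 4000,
                                  seed = 3)
  fit <- fit_progress_curves(cur, "product_inhibition")
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  expect_equal(unname(est["Ki"]), 20, tolerance = 0.25)

  # fitting the plain model to strongly inhibited data leaves systematic
  # late-time residual runs
  strong <- simulate_progress_curves(0.9, 28, 0.2, c(40, 80), Ki = 2,
                                     noise_sd = 0.02, dt = 20, t_end = 6000,
                                     seed = 4)
  misfit <- fit_progress_curves(strong, "plain")
  runs <- residual_runs_test(misfit)
  expect_lt(runs$p_combined, 0.05)
})

test_that("global fit loss is no worse than the sum of per-curve fits", {
  cur <- simulate_progress_curves(1.2, 15, 0.1, c(10, 40, 120),
                                  noise_sd = 0.1, dt = 20, t_end = 2500,
                                  seed = 6)
  fit <- fit_progress_curves(cur, "plain")
  per_curve <- sum(vapply(split(cur, cur$curve_id), function(cc) {
    fit_progress_curves(cc, "plain")$deviance
  }, numeric(1)))
  expect_gte(fit$deviance + 1e-6, per_curve)
  # ... and evaluating the global parameters per curve reproduces the
  # global loss (sanity of the shared-parameter objective)
  est <- stats::setNames(fit$params$estimate, fit$params$term)
  manual <- sum(vapply(split(cur, cur$curve_id), function(cc) {
    pred <- integrated_mm_product(cc$t_s, est["kcat"], est["KM"],
                                  cc$E0_uM[1], cc$S0_uM[1])
    sum((cc$P_uM - pred)^2)
  }, numeric(1)))
  expect_equal(fit$deviance, manual, tolerance = 1e-6)
})

test_that("rank concordance matches direct computation on printed values", {
  # reconstructed ancestors: TrpF efficiencies vs TrpF complementation times
  kin <- extant_kinetics()
  eff <- kin$eff_Ms[kin$reaction == "TrpF" & grepl("^CA-", kin$enzyme)]
  names(eff) <- kin$enzyme[kin$reaction == "TrpF" & grepl("^CA-", kin$enzyme)]
  tms <- complementation_times()
  times <- stats::setNames(tms$delta_trpF_h, tms$enzyme)
  expect_equal(rank_concordance(eff, times), -1)
  # identical rankings
  expect_equal(rank_concordance(c(a = 1, b = 2, c = 3),
                                c(a = 10, b = 20, c = 30)), 1)
  # one adjacent swap among 3 -> rho = 0.5
  expect_equal(rank_concordance(c(a = 1, b = 2, c = 3),
                                c(a = 20, b = 10, c = 30)), 0.5)
  expect_error(rank_concordance(c(a = 1, b = 2), c(a = 1, b = 2)),
               class = "hisatrace_invalid_argument")
})
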