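# Equal-mean (transcription) and volume-scaled (concentration) homeostasis.

test_that("every partner rate restores equal stage means", {
  set.seed(61)
  for (i in 1:100) {
    base <- stage_kinetics(runif_log(1, 0.05, 5), runif_log(1, 0.05, 5),
                           runif_log(1, 0.5, 50), runif_log(1, 0.05, 5))
    cyc <- cell_cycle_rates(runif_log(1, 0.02, 2), runif_log(1, 0.02, 2))
    for (w in c("nu", "delta", "lambda")) {
      sm <- stationary_means(homeostasis_params(w, base, cyc))
      expect_lt(abs(sm$m1_star - sm$m2_star) / sm$m1_star, 1e-10)
    }
    g2 <- tryCatch(homeostasis_partner_rate("gamma", base, cyc),
                   error = function(e) NA_real_)
    if (!is.na(g2)) {
      sm <- stationary_means(homeostasis_params("gamma", base, cyc))
      expect_lt(abs(sm$m1_star - sm$m2_star) / sm$m1_star, 1e-10)
    }
  }
})

test_that("frozen-cycle limits: halve synthesis, or double gamma plus lambda", {
  base <- stage_kinetics(1.3, 0.8, 20, 0.5)
  cyc <- cell_cycle_rates(1e-12, 1e-12)
  expect_equal(homeostasis_partner_rate("nu", base, cyc), 20 / 2,
               tolerance = 1e-9)
  g2 <- homeostasis_partner_rate("gamma", base, cyc)
  expect_equal(g2, 2 * 0.8 + 1.3, tolerance = 1e-9)
  # active-fraction balance: one copy at lambda/(lambda+gamma1) matches two
  # copies at lambda/(lambda+gamma2) each
  expect_equal(1.3 / (1.3 + 0.8), 2 * 1.3 / (1.3 + g2), tolerance = 1e-9)
  expect_equal(homeostasis_partner_rate("delta", base, cyc), 2 * 0.5,
               tolerance = 1e-9)
})

test_that("gamma-axis homeostasis can be infeasible and says so", {
  base <- stage_kinetics(1, 1, 5, 0.1)
  expect_error(homeostasis_partner_rate("gamma", base, cell_cycle_rates(0.01, 500)),
               "infeasible")
})

test_that("the residual carries the sign of m1* - m2*", {
  set.seed(71)
  for (i in 1:50) {
    p <- random_params()
    sm <- stationary_means(p)
    expect_identical(sign(homeostasis_residual(p)),
                     sign(sm$m1_star - sm$m2_star))
  }
  # shared kinetics sit in the r* > 1 regime: negative residual
  expect_lt(homeostasis_residual(baseline_params()), 0)
  expect_equal(homeostasis_residual(homeostasis_params("nu", mesc_kinetics(),
                                                       mesc_cycle())),
               0, tolerance = 1e-6)
})

test_that("exponential growth doubles the expected division volume", {
  vm <- volume_growth(cell_cycle_rates(1, 1))
  expect_equal(vm$r_v, sqrt(2), tolerance = 1e-12)
  # r_v in (1, 2); a long S1 (small kappa1) pushes it toward 1
  k1s <- exp(seq(log(0.01), log(10), length.out = 30))
  rvs <- vapply(k1s, function(k1) volume_growth(cell_cycle_rates(k1, 0.3))$r_v,
                numeric(1))
  expect_true(all(rvs > 1 & rvs < 2))
  expect_true(all(diff(rvs) > 0))
  expect_equal(volume_growth(cell_cycle_rates(1e-9, 0.3))$r_v, 1,
               tolerance = 1e-6)
  expect_equal(volume_growth(cell_cycle_rates(0.3, 1e-9))$r_v, 2,
               tolerance = 1e-6)
  # Monte Carlo: E[exp(a (T1+T2))] = 2 and E[exp(a T1)] = kappa1/(kappa1-a)
  cyc <- cell_cycle_rates(0.4, 1.1)
  vm <- volume_growth(cyc)
  set.seed(10)
  t1 <- rexp(1e6, cyc$kappa1); t2 <- rexp(1e6, cyc$kappa2)
  v_div <- exp(vm$a * (t1 + t2))
  expect_lt(abs(mean(v_div) - 2), 3 * stats::sd(v_div) / sqrt(1e6))
  v_t1 <- exp(vm$a * t1)
  expect_lt(abs(mean(v_t1) - vm$EV_T1), 3 * stats::sd(v_t1) / sqrt(1e6))
})

test_that("the cycle-length distribution is hypoexponential with Erlang limit", {
  cyc <- cell_cycle_rates(0.5, 1.5)
  expect_equal(cycle_length_cdf(0, cyc), 0)
  # continuity at kappa1 = kappa2: closed Erlang form vs nearby unequal rates
  t <- c(0.5, 2, 7)
  eq <- cycle_length_cdf(t, cell_cycle_rates(1, 1))
  expect_equal(eq, 1 - exp(-t) * (1 + t), tolerance = 1e-12)
  near <- cycle_length_cdf(t, cell_cycle_rates(1, 1 + 1e-6))
  expect_equal(near, eq, tolerance = 1e-5)
  # empirical CDF of sampled cycle lengths
  set.seed(12)
  x <- rcycle_length(1e6, cyc)
  grid <- seq(0, 20, by = 0.01)
  emp <- stats::ecdf(x)(grid)
  expect_lt(max(abs(emp - cycle_length_cdf(grid, cyc))), 0.002)
})

test_that("concentration homeostasis pins the S2 burst frequency", {
  p <- model_params(mesc_kinetics(), cycle = mesc_cycle())
  l2 <- solve_concentration_homeostasis("lambda", p)
  expect_equal(l2, 0.3164, tolerance = 2e-3)
  # substituting back satisfies r* = r_v to solver precision
  p2 <- model_params(p$stage1,
                     stage_kinetics(l2, p$stage1$gamma, p$stage1$nu, p$stage1$delta),
                     cycle = p$cycle)
  expect_lt(abs(fold_change(p2) - volume_growth(p$cycle)$r_v), 1e-10)
  # a bracket with no crossing is an error, not a silent extrapolation
  expect_error(solve_concentration_homeostasis("lambda", p, bracket = c(10, 1000)),
               "no sign change")
})

test_that("solved burst-frequency reduction is robust across S1 durations", {
  p0 <- model_params(mesc_kinetics(), cycle = mesc_cycle())
  s1_hours <- seq(2, 10, length.out = 9)
  l2 <- vapply(s1_hours, function(h) {
    solve_concentration_homeostasis(
      "lambda", model_params(p0$stage1, cycle = cell_cycle_rates(1 / h, 60 / 220)))
  }, numeric(1))
  expect_true(all(l2 > 0.315 - 0.005 & l2 < 0.355 + 0.005))
  # gamma route: equalized burst frequency, larger burst size in S2
  g2 <- vapply(s1_hours, function(h) {
    base <- mesc_kinetics()
    p <- model_params(base,
                      stage_kinetics(base$lambda / 2, base$gamma, base$nu, base$delta),
                      cycle = cell_cycle_rates(1 / h, 60 / 220))
    solve_concentration_homeostasis("gamma", p)
  }, numeric(1))
  expect_true(all(g2 > 0.78 - 0.005 & g2 < 0.92 + 0.005))
})

test_that("homeostasis point and noise minimum sit close on the nu axis", {
  p <- model_params(mesc_kinetics(), cycle = mesc_cycle())
  hz <- find_homeostasis_and_noise_minimum("nu", p)
  ratio54 <- homeostasis_partner_rate("nu", p$stage1, p$cycle) / p$stage1$nu
  expect_equal(hz$H_ratio, ratio54, tolerance = 1e-9)
  expect_lt(abs(log(hz$H_ratio) - log(hz$Z_ratio)), 0.7)
  # frozen-cycle degradation axis: homeostasis at exactly double turnover
  pslow <- model_params(mesc_kinetics(), cycle = cell_cycle_rates(1e-10, 1e-10))
  hz2 <- find_homeostasis_and_noise_minimum("delta", pslow)
  expect_equal(hz2$H_ratio, 2, tolerance = 1e-6)
})
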