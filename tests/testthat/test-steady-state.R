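# Closed-form stationary moments, noise, and the fold-change theory.

test_that("stage means obey the occupancy mixture and vanish without synthesis", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_params()
    s <- steady_state(p)
    w <- p$cycle$kappa2 / (p$cycle$kappa1 + p$cycle$kappa2)
    expect_equal(s$m_star, s$m1_star * w + s$m2_star * (1 - w),
                 tolerance = 1e-14)
    expect_equal(s$mu_star, s$mu1_star * w + s$mu2_star * (1 - w),
                 tolerance = 1e-14)
    expect_true(all(c(s$m1_star, s$m2_star, s$mu1_star, s$mu2_star) >= 0))
    # variances non-negative
    expect_gte(s$mu1_star, s$m1_star^2)
    expect_gte(s$mu2_star, s$m2_star^2)
    expect_gte(s$mu_star, s$m_star^2)
    expect_gt(s$p22_star, 0); expect_lt(s$p22_star, 1)
  }
  # means are linear in synthesis, so they vanish in the nu -> 0 limit
  tiny <- model_params(stage_kinetics(1, 2, 1e-12, 1),
                       cycle = cell_cycle_rates(0.5, 0.5))
  expect_lt(stationary_means(tiny)$m_star, 1e-11)
})

test_that("slow cycling recovers the one-copy telegraph mean and Fano factor", {
  k <- mesc_kinetics()
  lim <- slow_cycling_limits(k)
  expect_equal(lim$m1_limit, 113.4 * 0.5556 / (0.14 * (0.5556 + 1.0714)),
               tolerance = 1e-12)
  expect_equal(lim$m1_limit, 276.6, tolerance = 1e-3)
  expect_equal(lim$phi_limit,
               1 + 113.4 * 1.0714 / ((0.5556 + 1.0714) * (0.14 + 0.5556 + 1.0714)),
               tolerance = 1e-12)
  # full formulas at nearly-frozen cycling reproduce both limits
  p <- model_params(k, cycle = cell_cycle_rates(1e-9, 1e-9))
  s <- steady_state(p)
  expect_equal(rel_err(s$m1_star, lim$m1_limit), 0, tolerance = 1e-4)
  expect_equal(rel_err(s$phi1, lim$phi_limit), 0, tolerance = 1e-4)
  expect_equal(rel_err(s$phi2, lim$phi_limit), 0, tolerance = 1e-4)
  # second-moment slow-cycling limit of the S1 branch
  mu1_lim <- with(k, nu * lambda / (delta * (lambda + gamma)) *
                    (1 + nu * (delta + lambda) / (delta * (delta + lambda + gamma))))
  expect_equal(rel_err(s$mu1_star, mu1_lim), 0, tolerance = 1e-4)
  # vanishing inactivation -> Poisson (Fano 1)
  p0 <- model_params(stage_kinetics(1, 1e-12, 5, 1),
                     cycle = cell_cycle_rates(1e-9, 1e-9))
  expect_equal(steady_state(p0)$phi1, 1, tolerance = 1e-6)
})

test_that("fold change from the means equals its direct closed form", {
  set.seed(23)
  for (i in 1:1000) {
    p <- random_params()
    sm <- stationary_means(p)
    expect_equal(rel_err(fold_change(p), sm$m2_star / sm$m1_star), 0,
                 tolerance = 1e-12)
  }
})

test_that("all stationary quantities are invariant under time-unit rescaling", {
  set.seed(31)
  p <- random_params()
  ref <- glance(steady_state(p))
  for (c0 in c(1 / 60, 7.3)) {
    u <- tibble::as_tibble(p)
    ps <- model_params(
      stage_kinetics(u$lambda1 * c0, u$gamma1 * c0, u$nu1 * c0, u$delta1 * c0),
      stage_kinetics(u$lambda2 * c0, u$gamma2 * c0, u$nu2 * c0, u$delta2 * c0),
      cycle = cell_cycle_rates(u$kappa1 * c0, u$kappa2 * c0)
    )
    expect_equal(as.numeric(glance(steady_state(ps))), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("shared kinetics with equal stage rates give r* = (2d+3k)/(d+2k)", {
  p <- model_params(stage_kinetics(1.3, 0.7, 5, 0.14),
                    cycle = cell_cycle_rates(8e-4, 8e-4))
  expect_equal(fold_change(p), (2 * 0.14 + 3 * 8e-4) / (0.14 + 2 * 8e-4),
               tolerance = 1e-12)
  expect_equal(fold_change(p), 1.9944, tolerance = 1e-4)
})

test_that("constitutive limit: doubling at slow division, scale invariance", {
  # kappa2 -> 0: the cell spends forever with two copies -> r* -> 2
  r <- constitutive_fold_change(3, 3, 1, 0.5, 1e-10)$r_star
  expect_equal(r, 2, tolerance = 1e-9)
  # the fold change is homogeneous of degree zero
  a <- constitutive_fold_change(151.2, 128.4, 1.18, 60 / 53, 60 / 17)
  b <- constitutive_fold_change(151.2 / 60, 128.4 / 60, 1.18 / 60, 1 / 53, 1 / 17)
  expect_equal(a$r_star, b$r_star, tolerance = 1e-12)
  expect_error(constitutive_fold_change(1, 1, -1, 1, 1), "delta")
})

test_that("prescribed fold changes are reached under shared kinetics", {
  for (C in c(0.25, 0.5, 1)) {
    p <- design_fold_change(C, kappa1 = 1)
    expect_equal(rel_err(fold_change(p), C), 0, tolerance = 1e-12)
    # shared kinetics by construction
    expect_identical(p$stage1, p$stage2)
  }
  # closed-form witness for C = 1: lambda+gamma = kappa1, kappa2 = 4, delta = 2
  p1 <- design_fold_change(1, kappa1 = 1)
  expect_equal(p1$cycle$kappa2, 4)
  expect_equal(p1$stage1$delta, 2)
  # C = 0.5 requires kappa2 = 8 kappa1 >= 4 (lambda + gamma)
  p05 <- design_fold_change(0.5, kappa1 = 1)
  expect_equal(p05$cycle$kappa2, 8)
  expect_gte(p05$cycle$kappa2, 4 * (p05$stage1$lambda + p05$stage1$gamma))
  for (C in c(1.5, 3, 12)) {
    expect_equal(rel_err(fold_change(design_fold_change(C)), C), 0,
                 tolerance = 1e-9)
  }
  expect_error(design_fold_change(-1), "positive")
})

test_that("regime thresholds separate r* > 2 and r* < 1 exactly", {
  k <- stage_kinetics(0.8, 0.827, 5, 0.14) # lambda + gamma = 1.627
  # threshold in kappa1 at kappa2 = 0.1: 0.1 + 0.1 * 1.727 / 0.28
  thr <- 0.1 + 0.1 * (0.1 + 1.627) / (2 * 0.14)
  expect_equal(fold_change_regime(k, cell_cycle_rates(1, 0.1))$kappa1_threshold,
               thr, tolerance = 1e-12)
  expect_gt(fold_change_regime(k, cell_cycle_rates(0.75, 0.1))$r_star, 2)
  expect_lt(fold_change_regime(k, cell_cycle_rates(0.70, 0.1))$r_star, 2)
  # kappa1 = kappa2 always sits below the doubling regime
  rg <- fold_change_regime(k, cell_cycle_rates(0.3, 0.3))
  expect_false(rg$gt2)
  expect_lt(rg$r_star, 2)
  # very fast S2 turnover pushes the fold change below one
  rg2 <- fold_change_regime(k, cell_cycle_rates(0.3, 500))
  expect_true(rg2$lt1)
  expect_lt(rg2$r_star, 1)
})

test_that("fold change is unimodal in kappa1 and U-shaped in kappa2", {
  k <- stage_kinetics(0.5556, 1.0714, 5, 0.14)
  r_of <- function(k1, k2) fold_change(model_params(k, cycle = cell_cycle_rates(k1, k2)))
  # sweep kappa1 at fixed kappa2: rises to a unique peak, then decays to 2
  k1s <- exp(seq(log(1e-4), log(1e4), length.out = 120))
  r1 <- vapply(k1s, r_of, numeric(1), k2 = 0.1)
  d1 <- sign(diff(r1))
  expect_equal(sum(diff(d1) != 0), 1) # one sign change: single interior peak
  expect_equal(r1[length(r1)], 2, tolerance = 1e-3)
  # sweep kappa2 at fixed kappa1: falls to a unique trough, then climbs to 1
  k2s <- exp(seq(log(1e-4), log(1e6), length.out = 140))
  r2 <- vapply(k2s, r_of, numeric(1), k1 = 0.5)
  d2 <- sign(diff(r2))
  expect_equal(sum(diff(d2) != 0), 1)
  expect_equal(r2[length(r2)], 1, tolerance = 1e-3)
  expect_gt(r2[1], 2)
})

test_that("noise measures satisfy Phi = eta2 * mean and error at zero mean", {
  set.seed(47)
  for (i in 1:20) {
    s <- steady_state(random_params())
    expect_equal(s$phi1, s$eta2_1 * s$m1_star, tolerance = 1e-12)
    expect_equal(s$phi2, s$eta2_2 * s$m2_star, tolerance = 1e-12)
    expect_equal(s$phi, s$eta2 * s$m_star, tolerance = 1e-12)
  }
  tb <- tidy(steady_state(baseline_params()))
  expect_identical(nrow(tb), 16L)
})
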