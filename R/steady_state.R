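# Closed-form stationary moments of the cell-cycle-coupled telegraph model.
#
# All formulas are evaluated exactly as published (no algebraic
# re-simplification), and are adjudicated against the truncated
# master-equation solver in the test suite.

steady_core <- function(params) {
  with(unpack(params), {
    den1 <- (2 * (d1 + k1) * (d2 + k2) - k1 * k2) *
      (l1 + g1 + k1) * (l2 + g2 + k2)
    m1 <- (2 * v1 * l1 * (d2 + k2) * (l2 + g2 + k2) +
             2 * v2 * l2 * k1 * (l1 + g1 + k1)) / den1
    m2 <- (2 * v1 * l1 * k2 * (l2 + g2 + k2) +
             4 * v2 * l2 * (d1 + k1) * (l1 + g1 + k1)) / den1
    m <- m1 * k2 / (k1 + k2) + m2 * k1 / (k1 + k2)

    p22 <- 2 * l2^2 / ((k2 + l2 + g2) * (k2 + 2 * l2 + 2 * g2))
    ms1 <- ((d1 + l1 + k1) * m1 - k1 * m2 / 2) / (d1 + l1 + g1 + k1)
    ms2 <- ((d2 + k2 + 2 * l2) * m2 - k2 * m1 + 2 * v2 * p22) /
      (d2 + l2 + g2 + k2)
    den2 <- 4 * (k1 + 2 * d1) * (k2 + 2 * d2) - k1 * k2
    mu1 <- m1 + (8 * v1 * (k2 + 2 * d2) * ms1 + 2 * v2 * k1 * ms2) / den2
    mu2 <- m2 + (8 * v1 * k2 * ms1 + 8 * v2 * (k1 + 2 * d1) * ms2) / den2
    mu <- mu1 * k2 / (k1 + k2) + mu2 * k1 / (k1 + k2)

    list(m1_star = m1, m2_star = m2, m_star = m,
         mu1_star = mu1, mu2_star = mu2, mu_star = mu,
         ms1_star = ms1, ms2_star = ms2, p22_star = p22)
  })
}

#' Stationary moments, noise and fold change
#'
#' Evaluates the closed-form steady state of the telegraph model coupled to
#' the two-stage cell cycle: stage-conditioned and population means
#' (`m1_star`, `m2_star`, `m_star`), second moments (`mu1_star`, `mu2_star`,
#' `mu_star`), noise (squared coefficient of variation, `eta2_*`), noise
#' strength (variance-to-mean Fano statistic, `phi*`), and the S1 -> S2 fold
#' change `r_star = m2_star / m1_star`. The population values are the
#' stationary stage-occupancy mixtures
#' `m_star = m1_star * kappa2/(kappa1+kappa2) + m2_star * kappa1/(kappa1+kappa2)`
#' (and likewise for `mu_star`).
#'
#' @param params A [model_params()] object.
#' @return An object of class `telecycle_steady`; use [tidy()] for a long
#'   tibble of all quantities or [glance()] for a one-row summary.
#' @examples
#' p <- model_params(stage_kinetics(1, 2, 5, 1), cycle = cell_cycle_rates(0.5, 0.5))
#' glance(steady_state(p))
#' @export
steady_state <- function(params) {
  core <- steady_core(params)
  noise <- with(core, {
    if (m1_star <= 0 || m2_star <= 0 || m_star <= 0) {
      abort("noise measures are undefined at zero mean (nu must be positive)")
    }
    list(phi1 = (mu1_star - m1_star^2) / m1_star,
         phi2 = (mu2_star - m2_star^2) / m2_star,
         phi  = (mu_star  - m_star^2)  / m_star,
         eta2_1 = (mu1_star - m1_star^2) / m1_star^2,
         eta2_2 = (mu2_star - m2_star^2) / m2_star^2,
         eta2   = (mu_star  - m_star^2)  / m_star^2)
  })
  structure(c(core, noise, list(r_star = core$m2_star / core$m1_star,
                                params = params)),
            class = "telecycle_steady")
}

#' @export
print.telecycle_steady <- function(x, ...) {
  cat("<telecycle_steady>\n")
  cat(sprintf("  means      m1*=%.6g  m2*=%.6g  m*=%.6g\n",
              x$m1_star, x$m2_star, x$m_star))
  cat(sprintf("  noise eta2 S1=%.6g  S2=%.6g  pop=%.6g\n",
              x$eta2_1, x$eta2_2, x$eta2))
  cat(sprintf("  Fano  Phi  S1=%.6g  S2=%.6g  pop=%.6g\n",
              x$phi1, x$phi2, x$phi))
  cat(sprintf("  fold change r* = %.6g\n", x$r_star))
  invisible(x)
}

steady_fields <- c("m1_star", "m2_star", "m_star",
                   "mu1_star", "mu2_star", "mu_star",
                   "ms1_star", "ms2_star", "p22_star",
                   "eta2_1", "eta2_2", "eta2",
                   "phi1", "phi2", "phi", "r_star")

#' @rdname steady_state
#' @param x A `telecycle_steady` object.
#' @param ... Unused.
#' @export
tidy.telecycle_steady <- function(x, ...) {
  tibble(quantity = steady_fields,
         value = vapply(steady_fields, function(f) x[[f]], numeric(1)))
}

#' @rdname steady_state
#' @export
glance.telecycle_steady <- function(x, ...) {
  as_tibble(setNames(as.list(vapply(steady_fields, function(f) x[[f]],
                                    numeric(1))), steady_fields))
}

#' @describeIn steady_state Stage-conditioned and population stationary means
#'   only, as a one-row tibble.
#' @export
stationary_means <- function(params) {
  core <- steady_core(params)
  tibble(m1_star = core$m1_star, m2_star = core$m2_star, m_star = core$m_star)
}

#' @describeIn steady_state Stationary second moments and the intermediate
#'   quantities of the closed form, as a one-row tibble.
#' @export
stationary_second_moments <- function(params) {
  core <- steady_core(params)
  as_tibble(core[c("mu1_star", "mu2_star", "mu_star",
                   "ms1_star", "ms2_star", "p22_star")])
}

#' @describeIn steady_state Noise (eta^2, dimensionless) and noise strength
#'   (Phi, mRNA-count units) per stage and for the population.
#' @export
noise_measures <- function(params) {
  s <- steady_state(params)
  tibble(eta2_1 = s$eta2_1, eta2_2 = s$eta2_2, eta2 = s$eta2,
         phi1 = s$phi1, phi2 = s$phi2, phi = s$phi)
}

#' Fold change of the mean mRNA count from S1 to S2
#'
#' The stationary fold change `r_star = m2_star / m1_star`, evaluated from
#' its direct closed form in the ten model rates. Homogeneous of degree zero:
#' rescaling all rates by a common factor leaves it unchanged.
#'
#' @param params A [model_params()] object.
#' @return The dimensionless fold change `r_star`.
#' @examples
#' # shared kinetics, equal stage transition rates: r* = (2 delta + 3 kappa)/(delta + 2 kappa)
#' p <- model_params(stage_kinetics(1, 2, 5, 0.14), cycle = cell_cycle_rates(8e-4, 8e-4))
#' fold_change(p)
#' @export
fold_change <- function(params) {
  with(unpack(params), {
    (v1 * l1 * k2 * (l2 + g2 + k2) + 2 * v2 * l2 * (d1 + k1) * (l1 + g1 + k1)) /
      (v1 * l1 * (d2 + k2) * (l2 + g2 + k2) + v2 * l2 * k1 * (l1 + g1 + k1))
  })
}

#' Slow-cycling limits of the stage-1 mean and Fano factor
#'
#' When the stage transition rates tend to zero with kinetics shared between
#' stages, the S1 mean tends to the classical one-copy telegraph value
#' `nu*lambda / (delta*(lambda+gamma))` and both stage Fano factors tend to
#' `1 + nu*gamma / ((lambda+gamma)*(delta+lambda+gamma))`.
#'
#' @param kinetics A [stage_kinetics()] object (shared by both stages).
#' @return A one-row tibble with columns `m1_limit` and `phi_limit`.
#' @export
slow_cycling_limits <- function(kinetics) {
  stopifnot(inherits(kinetics, "stage_kinetics"))
  with(kinetics, tibble(
    m1_limit = nu * lambda / (delta * (lambda + gamma)),
    phi_limit = 1 + nu * gamma / ((lambda + gamma) * (delta + lambda + gamma))
  ))
}

#' Means and fold change in the constitutive (always-on promoter) limit
#'
#' With activation rates taken to infinity every gene copy transcribes
#' constitutively and the stationary means reduce to
#' `m1* = (2 nu1 (delta+kappa2) + 2 nu2 kappa1) / (2(delta+kappa1)(delta+kappa2) - kappa1 kappa2)`,
#' `m2* = (2 nu1 kappa2 + 4 nu2 (delta+kappa1)) / (same denominator)`, with
#' fold change
#' `r* = (nu1 kappa2 + 2 nu2 (delta+kappa1)) / (nu1 (delta+kappa2) + nu2 kappa1)`.
#' Used to study how the timing of gene duplication inside a cycle of fixed
#' average length moves the fold change.
#'
#' @param nu1,nu2 Synthesis rates per copy in S1 and S2 (hr^-1).
#' @param delta mRNA degradation rate (hr^-1), shared.
#' @param kappa1,kappa2 Stage transition rates (hr^-1).
#' @return A one-row tibble with `m1_star`, `m2_star`, `r_star`.
#' @examples
#' constitutive_fold_change(151.2, 128.4, 1.18, 60 / 53, 60 / 17)
#' @export
constitutive_fold_change <- function(nu1, nu2, delta, kappa1, kappa2) {
  check_positive_rates(c(nu1 = nu1, nu2 = nu2, delta = delta,
                         kappa1 = kappa1, kappa2 = kappa2),
                       "constitutive_fold_change")
  den <- 2 * (delta + kappa1) * (delta + kappa2) - kappa1 * kappa2
  tibble(
    m1_star = (2 * nu1 * (delta + kappa2) + 2 * nu2 * kappa1) / den,
    m2_star = (2 * nu1 * kappa2 + 4 * nu2 * (delta + kappa1)) / den,
    r_star = (nu1 * kappa2 + 2 * nu2 * (delta + kappa1)) /
      (nu1 * (delta + kappa2) + nu2 * kappa1)
  )
}

#' Construct a shared-kinetics parameter set with a prescribed fold change
#'
#' Any positive fold change can be realised even when the telegraph kinetics
#' are identical in both stages. For a target `C <= 1` the closed-form
#' witness sets `lambda + gamma = kappa1`, `kappa2 = 4 kappa1 / C` and
#' `delta = (16 - 12 C - 2 C^3) kappa1 / C^3`. For `C > 1` no closed form is
#' published; the constructor fixes `lambda + gamma = kappa1 / C^2` and
#' `delta = kappa1 * C^2` (a family whose fold change exceeds `C` as
#' `kappa2 -> 0` and tends to 1 as `kappa2 -> Inf`) and root-finds `kappa2`.
#'
#' @param C Target fold change, positive.
#' @param kappa1 Reference S1 -> S2 rate (hr^-1).
#' @param nu Synthesis rate to embed in the returned parameter set (the fold
#'   change is independent of `nu` under shared kinetics).
#' @param tol Relative tolerance on the achieved fold change.
#' @return A [model_params()] object `p` with shared kinetics and
#'   `fold_change(p) == C` to within `tol`.
#' @examples
#' p <- design_fold_change(0.5, kappa1 = 1)
#' fold_change(p) # 0.5
#' @export
design_fold_change <- function(C, kappa1 = 1, nu = 1, tol = 1e-12) {
  if (!is.finite(C) || C <= 0) abort("target fold change C must be positive")
  shared <- function(lg, delta, k2) {
    model_params(stage_kinetics(lg / 2, lg / 2, nu, delta),
                 cycle = cell_cycle_rates(kappa1, k2))
  }
  if (C <= 1) {
    delta <- (16 - 12 * C - 2 * C^3) * kappa1 / C^3
    return(shared(kappa1, delta, 4 * kappa1 / C))
  }
  lg <- kappa1 / C^2
  delta <- kappa1 * C^2
  f <- function(log_k2) fold_change(shared(lg, delta, exp(log_k2))) - C
  root <- uniroot(f, lower = log(kappa1) - 25, upper = log(kappa1) + 25,
                  tol = .Machine$double.eps^0.9)$root
  p <- shared(lg, delta, exp(root))
  if (abs(fold_change(p) - C) / C > tol) {
    abort(sprintf("fold-change construction for C = %g missed the target", C))
  }
  p
}

#' Fold-change regime under shared kinetics
#'
#' With kinetics shared between stages, the fold change exceeds 2 if and only
#' if `kappa1 > kappa2 + kappa2 (kappa2 + lambda + gamma) / (2 delta)`, and
#' drops below 1 if and only if
#' `kappa2 > 2 kappa1 + lambda + gamma + kappa1 (lambda + gamma + kappa1) / delta`.
#' Whenever `kappa1 <= kappa2` the fold change is strictly below 2.
#'
#' @param kinetics A [stage_kinetics()] object shared by both stages.
#' @param cycle A [cell_cycle_rates()] object.
#' @return A one-row tibble with the fold change `r_star`, the logical flags
#'   `gt2` and `lt1`, and the two threshold values of `kappa1` and `kappa2`.
#' @export
fold_change_regime <- function(kinetics, cycle) {
  stopifnot(inherits(kinetics, "stage_kinetics"),
            inherits(cycle, "cell_cycle_rates"))
  lg <- kinetics$lambda + kinetics$gamma
  delta <- kinetics$delta
  k1 <- cycle$kappa1
  k2 <- cycle$kappa2
  thr1 <- k2 + k2 * (k2 + lg) / (2 * delta)   # r* > 2 iff kappa1 > thr1
  thr2 <- 2 * k1 + lg + k1 * (lg + k1) / delta # r* < 1 iff kappa2 > thr2
  r <- fold_change(model_params(kinetics, cycle = cycle))
  tibble(r_star = r, gt2 = k1 > thr1, lt1 = k2 > thr2,
         kappa1_threshold = thr1, kappa2_threshold = thr2)
}
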