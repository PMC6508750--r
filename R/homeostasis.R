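# Transcription homeostasis (equal stage means) and transcript
# concentration homeostasis (mean scales with cell volume).

#' Partner rate restoring equal stage means
#'
#' Transcription homeostasis is defined as `m1_star = m2_star`: the mean
#' transcript count is unchanged by gene duplication. If a single kinetic
#' rate is allowed to differ between stages while its partner and all other
#' rates are shared, the S2 value that restores homeostasis is available in
#' closed form:
#' \describe{
#'   \item{nu}{`nu2 = nu1 * delta * (lambda+gamma+kappa2) /
#'     ((2*delta+kappa1) * (lambda+gamma+kappa1))` — halve synthesis (in the
#'     slow-cycling limit) to offset the dosage doubling.}
#'   \item{delta}{`delta2 = (2*delta1+kappa1) * (lambda+gamma+kappa1) /
#'     (lambda+gamma+kappa2)`.}
#'   \item{lambda}{`1/lambda2 = (1/lambda1) * (2*delta+kappa1)*(gamma+kappa1)
#'     / (delta*(gamma+kappa2)) + (delta+kappa1)/(delta*(gamma+kappa2))`.}
#'   \item{gamma}{`gamma2 = gamma1*(2*delta+kappa1)/delta +
#'     (delta*lambda + 2*delta*kappa1 + lambda*kappa1 + kappa1^2 -
#'     delta*kappa2)/delta`, which can be non-positive (infeasible) for
#'     large `kappa2`.}
#' }
#'
#' @param which Which rate pair differs between stages: `"nu"`, `"delta"`,
#'   `"lambda"` or `"gamma"`.
#' @param base A [stage_kinetics()] object holding the S1 value of the varied
#'   rate and the stage-independent values of the other three.
#' @param cycle A [cell_cycle_rates()] object.
#' @return The S2 value of the varied rate (hr^-1).
#' @examples
#' k <- stage_kinetics(0.5556, 1.0714, 113.4, 0.14)
#' cyc <- cell_cycle_rates(60 / 560, 60 / 220)
#' homeostasis_partner_rate("nu", k, cyc)
#' @export
homeostasis_partner_rate <- function(which = c("nu", "delta", "lambda", "gamma"),
                                     base, cycle) {
  which <- arg_match(which)
  stopifnot(inherits(base, "stage_kinetics"), inherits(cycle, "cell_cycle_rates"))
  l <- base$lambda; g <- base$gamma; v <- base$nu; d <- base$delta
  k1 <- cycle$kappa1; k2 <- cycle$kappa2
  out <- switch(which,
    nu = v * d * (l + g + k2) / ((2 * d + k1) * (l + g + k1)),
    delta = (2 * d + k1) * (l + g + k1) / (l + g + k2),
    lambda = 1 / ((1 / l) * (2 * d + k1) * (g + k1) / (d * (g + k2)) +
                    (d + k1) / (d * (g + k2))),
    gamma = g * (2 * d + k1) / d +
      (d * l + 2 * d * k1 + l * k1 + k1^2 - d * k2) / d
  )
  if (which == "gamma" && out <= 0) {
    abort(sprintf(
      "homeostasis is infeasible on the gamma axis here (gamma2 = %g <= 0)",
      out))
  }
  out
}

#' @describeIn homeostasis_partner_rate Full parameter set with the S2 rate
#'   replaced by its homeostasis partner value.
#' @export
homeostasis_params <- function(which = c("nu", "delta", "lambda", "gamma"),
                               base, cycle) {
  which <- arg_match(which)
  s2 <- unclass(base)
  s2[[which]] <- homeostasis_partner_rate(which, base, cycle)
  model_params(base, do.call(stage_kinetics, s2), cycle = cycle)
}

#' Signed residual of the transcription-homeostasis condition
#'
#' Zero exactly when `m1_star = m2_star`. Derived by clearing the common
#' denominator of the two stationary means, which leaves
#' `nu1*lambda1*delta2*(lambda2+gamma2+kappa2) -
#'  nu2*lambda2*(2*delta1+kappa1)*(lambda1+gamma1+kappa1)`.
#' The residual has the sign of `m1_star - m2_star`: positive when S1
#' out-produces S2 (`r_star < 1`), negative in the common `r_star > 1`
#' regime (e.g. under shared kinetics).
#'
#' @param params A [model_params()] object.
#' @return A signed scalar residual (rate^3 units; only the sign and zero
#'   crossing are meaningful).
#' @export
homeostasis_residual <- function(params) {
  with(unpack(params), {
    v1 * l1 * d2 * (l2 + g2 + k2) - v2 * l2 * (2 * d1 + k1) * (l1 + g1 + k1)
  })
}

#' Exponential volume growth over the cell cycle
#'
#' A newborn cell has volume 1 and grows as `V(t) = exp(a t)`; requiring the
#' expected volume at division to be 2 under exponentially distributed stage
#' durations fixes the growth rate
#' `a = (kappa1 + kappa2 - sqrt(kappa1^2 + kappa2^2)) / 2` and gives the
#' S1 -> S2 mean volume fold change
#' `r_v = kappa2 / (kappa2 - a)`, always inside (1, 2).
#'
#' @param cycle A [cell_cycle_rates()] object.
#' @return A one-row tibble with `a`, `r_v`, `kappa1`, `kappa2`, and the
#'   mean stage-1 volume ratio `EV_T1 = kappa1 / (kappa1 - a)`.
#' @examples
#' volume_growth(cell_cycle_rates(1, 1)) # r_v = sqrt(2)
#' @export
volume_growth <- function(cycle) {
  stopifnot(inherits(cycle, "cell_cycle_rates"))
  k1 <- cycle$kappa1; k2 <- cycle$kappa2
  a <- (k1 + k2 - sqrt(k1^2 + k2^2)) / 2
  tibble(a = a, r_v = k2 / (k2 - a), kappa1 = k1, kappa2 = k2,
         EV_T1 = k1 / (k1 - a))
}

#' Distribution of the total cell-cycle length
#'
#' The cycle length `T1 + T2` is the sum of two independent exponentials
#' (hypoexponential). For `kappa1 != kappa2`
#' `F(t) = 1 - kappa2/(kappa2-kappa1) exp(-kappa1 t)
#'           - kappa1/(kappa1-kappa2) exp(-kappa2 t)`;
#' the `kappa1 = kappa2 = kappa` case is the analytic Erlang limit
#' `F(t) = 1 - exp(-kappa t) (1 + kappa t)`.
#'
#' @param t Non-negative time(s), hours.
#' @param cycle A [cell_cycle_rates()] object.
#' @return `P(T1 + T2 <= t)`, same length as `t`.
#' @export
cycle_length_cdf <- function(t, cycle) {
  stopifnot(inherits(cycle, "cell_cycle_rates"))
  if (any(t < 0)) abort("t must be non-negative")
  k1 <- cycle$kappa1; k2 <- cycle$kappa2
  if (abs(k1 - k2) <= 1e-9 * (k1 + k2)) {
    k <- (k1 + k2) / 2
    1 - exp(-k * t) * (1 + k * t)
  } else {
    1 - k2 / (k2 - k1) * exp(-k1 * t) - k1 / (k1 - k2) * exp(-k2 * t)
  }
}

#' @describeIn cycle_length_cdf Draw cycle lengths `T1 + T2`.
#' @param n Number of samples.
#' @export
rcycle_length <- function(n, cycle) {
  stopifnot(inherits(cycle, "cell_cycle_rates"))
  rexp(n, cycle$kappa1) + rexp(n, cycle$kappa2)
}

#' Solve for concentration homeostasis
#'
#' Concentration homeostasis requires the mean transcript count to scale
#' with mean cell volume across the stages: `r_star = r_v`. Given all other
#' rates, this solves for the single S2 rate (`lambda2`, `gamma2`, `nu2` or
#' `delta2`) that satisfies the identity, by a coarse log-spaced scan over
#' the bracket followed by root refinement. No sign change is an error
#' reporting the scanned interval; several sign changes are an ambiguity
#' error listing every root.
#'
#' @param free_rate Which S2 rate to solve for.
#' @param params A [model_params()] object supplying every other rate (the
#'   current value of the free rate is ignored).
#' @param bracket Search interval for the free rate, hr^-1.
#' @param n_scan Number of log-spaced scan points used to locate the sign
#'   change.
#' @return The solved rate value (hr^-1).
#' @examples
#' k <- stage_kinetics(0.5556, 1.0714, 113.4, 0.14)
#' p <- model_params(k, cycle = cell_cycle_rates(60 / 560, 60 / 220))
#' solve_concentration_homeostasis("lambda", p) # ~0.316
#' @export
solve_concentration_homeostasis <- function(free_rate = c("lambda", "gamma", "nu", "delta"),
                                            params,
                                            bracket = c(1e-6, 1e3),
                                            n_scan = 200) {
  free_rate <- arg_match(free_rate)
  stopifnot(inherits(params, "model_params"))
  rv <- volume_growth(params$cycle)$r_v
  f <- function(x) {
    s2 <- unclass(params$stage2)
    s2[[free_rate]] <- x
    fold_change(model_params(params$stage1, do.call(stage_kinetics, s2),
                             cycle = params$cycle)) - rv
  }
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_scan))
  vals <- vapply(grid, f, numeric(1))
  flips <- which(vals[-1] * vals[-n_scan] <= 0 & is.finite(vals[-1]))
  if (length(flips) == 0) {
    abort(sprintf(
      "no sign change of r* - r_v for %s2 in [%g, %g]; nothing to solve",
      free_rate, bracket[1], bracket[2]))
  }
  roots <- vapply(flips, function(j) {
    uniroot(f, lower = grid[j], upper = grid[j + 1],
            tol = .Machine$double.eps^0.9)$root
  }, numeric(1))
  roots <- unique(signif(roots, 12))
  if (length(roots) > 1) {
    abort(sprintf("ambiguous: several roots for %s2: %s",
                  free_rate, paste(signif(roots, 6), collapse = ", ")))
  }
  roots[[1]]
}

#' Homeostasis point and noise minimum along a rate-ratio axis
#'
#' Varies a single S2/S1 rate ratio over `range` (all other rates fixed from
#' `params`, with the S2 rate tied to its S1 value through the ratio) and
#' locates H, the ratio at which transcription homeostasis
#' (`m1_star = m2_star`) holds, and Z, the ratio minimizing the population
#' noise `eta2` (golden-section refinement of a log-spaced grid).
#'
#' @param axis Which rate ratio to vary: `"nu"`, `"delta"`, `"lambda"` or
#'   `"gamma"` (the ratio is S2 value over S1 value).
#' @param params A [model_params()] object; the S1 kinetics and cycle rates
#'   are taken from it.
#' @param range Positive ratio range, default `c(0.1, 10)`.
#' @param n_grid Log-spaced grid size used to bracket the minimum.
#' @return A one-row tibble with `axis`, `H_ratio` (`NA` if no homeostasis
#'   root lies in the range), `Z_ratio`, and the population noise at each.
#' @export
find_homeostasis_and_noise_minimum <- function(axis = c("nu", "delta", "lambda", "gamma"),
                                               params, range = c(0.1, 10),
                                               n_grid = 200) {
  axis <- arg_match(axis)
  stopifnot(inherits(params, "model_params"), all(range > 0))
  at_ratio <- function(r) {
    s2 <- unclass(params$stage1)
    s2[[axis]] <- r * params$stage1[[axis]]
    model_params(params$stage1, do.call(stage_kinetics, s2),
                 cycle = params$cycle)
  }
  res <- function(r) homeostasis_residual(at_ratio(r))
  noise <- function(r) steady_state(at_ratio(r))$eta2

  lo <- log(range[1]); hi <- log(range[2])
  H <- tryCatch(
    exp(uniroot(function(x) res(exp(x)), lower = lo, upper = hi,
                tol = .Machine$double.eps^0.6)$root),
    error = function(e) NA_real_)
  grid <- exp(seq(lo, hi, length.out = n_grid))
  vals <- vapply(grid, noise, numeric(1))
  j <- which.min(vals)
  jlo <- max(1L, j - 1L); jhi <- min(n_grid, j + 1L)
  Z <- exp(optimize(function(x) noise(exp(x)),
                    lower = log(grid[jlo]), upper = log(grid[jhi]),
                    tol = 1e-10)$minimum)
  tibble(axis = axis,
         H_ratio = H, Z_ratio = Z,
         eta2_H = if (is.na(H)) NA_real_ else noise(H),
         eta2_Z = noise(Z))
}
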