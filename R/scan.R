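# Parameter sweeps over the closed-form steady state.

#' Build a duration grid over the two cell-cycle stages
#'
#' Cross of mean S1 and S2 stage durations (given in minutes, the customary
#' presentation) converted to transition rates in hr^-1.
#'
#' @param s1_min,s2_min Vectors of mean stage durations in minutes.
#' @return A tibble with columns `dur1_min`, `dur2_min`, `kappa1`, `kappa2`,
#'   row-major over `s1_min` (outer) and `s2_min` (inner).
#' @examples
#' duration_grid(c(10, 100, 1000), c(10, 100, 1000))
#' @export
duration_grid <- function(s1_min, s2_min) {
  stopifnot(all(s1_min > 0), all(s2_min > 0))
  g <- expand.grid(dur2_min = s2_min, dur1_min = s1_min,
                   KEEP.OUT.ATTRS = FALSE)
  tibble(dur1_min = g$dur1_min, dur2_min = g$dur2_min,
         kappa1 = 60 / g$dur1_min, kappa2 = 60 / g$dur2_min)
}

#' @describeIn duration_grid Log-spaced duration axis, in minutes.
#' @param from,to,n Endpoints (minutes) and number of points.
#' @export
log_durations <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Evaluate the steady state over a grid of parameter overrides
#'
#' Takes a data frame whose columns override any of the ten model rates
#' (`lambda1`, `gamma1`, `nu1`, `delta1`, `lambda2`, `gamma2`, `nu2`,
#' `delta2`, `kappa1`, `kappa2`; all hr^-1) and evaluates every closed-form
#' stationary quantity row by row, starting from the base parameter set
#' `params`. Rows are returned in the input order, so re-running a scan is
#' byte-reproducible. The volume fold change `r_v` is appended for
#' convenience when comparing against concentration homeostasis.
#'
#' @param grid A data frame of rate overrides; extra columns (e.g. duration
#'   labels from [duration_grid()]) are carried through.
#' @param params A [model_params()] object supplying the rates not present
#'   in `grid`.
#' @return A tibble: the input columns followed by all [steady_state()]
#'   fields and `r_v`.
#' @examples
#' p <- model_params(stage_kinetics(0.5556, 1.0714, 113.4, 0.14),
#'                   cycle = cell_cycle_rates(0.5, 0.5))
#' steady_state_scan(duration_grid(c(60, 600), c(60, 600)), p)
#' @export
steady_state_scan <- function(grid, params) {
  stopifnot(is.data.frame(grid), inherits(params, "model_params"))
  rate_cols <- intersect(names(grid), names(unpack_named(params)))
  base <- unpack_named(params)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    o <- base
    for (col in rate_cols) o[[col]] <- grid[[col]][r]
    p <- model_params(
      stage_kinetics(o$lambda1, o$gamma1, o$nu1, o$delta1),
      stage_kinetics(o$lambda2, o$gamma2, o$nu2, o$delta2),
      cycle = cell_cycle_rates(o$kappa1, o$kappa2)
    )
    out <- glance(steady_state(p))
    out$r_v <- volume_growth(p$cycle)$r_v
    out
  })
  dplyr::bind_cols(as_tibble(grid), dplyr::bind_rows(rows))
}

#' Fold change as the gene duplication time moves within a fixed cycle
#'
#' In the constitutive (always-active) limit the stationary means depend on
#' the duplication timing only through `kappa1 = 1/t_dup` and
#' `kappa2 = 1/(cycle_total - t_dup)`. This sweeps the duplication time
#' across the cycle and evaluates [constitutive_fold_change()] at each
#' point.
#'
#' @param nu1,nu2 Synthesis rates in S1 and S2, hr^-1 per copy.
#' @param delta Degradation rate, hr^-1.
#' @param cycle_total_min Total mean cycle length in minutes.
#' @param dup_times_min Vector of duplication times in minutes, strictly
#'   inside `(0, cycle_total_min)`.
#' @return A tibble with `dup_time_min`, `kappa1`, `kappa2`, `m1_star`,
#'   `m2_star`, `r_star`.
#' @examples
#' duplication_time_sweep(151.2, 128.4, 1.18, 70, c(35, 44, 53))
#' @export
duplication_time_sweep <- function(nu1, nu2, delta, cycle_total_min,
                                   dup_times_min) {
  if (any(dup_times_min <= 0) || any(dup_times_min >= cycle_total_min)) {
    abort("duplication times must lie strictly inside (0, cycle_total_min)")
  }
  k1 <- 60 / dup_times_min
  k2 <- 60 / (cycle_total_min - dup_times_min)
  out <- purrr::map2(k1, k2,
                     function(a, b) constitutive_fold_change(nu1, nu2, delta, a, b))
  dplyr::bind_cols(tibble(dup_time_min = dup_times_min, kappa1 = k1, kappa2 = k2),
                   dplyr::bind_rows(out))
}
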