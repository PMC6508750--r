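# Time-dependent moments from the synchronized initial condition.
#
# The joint stage-promoter probabilities, the promoter-resolved first
# moments and the stage-partitioned second moments together satisfy one
# 12-dimensional linear ODE system with constant coefficients, so the
# solution is computed exactly with a matrix exponential per output time
# (no step-size or tolerance tuning).

moment_matrix <- function(params) {
  u <- unpack(params)
  A <- matrix(0, 12, 12)
  nm <- c("P10", "P11", "P20", "P21", "P22",
          "n10", "n11", "n20", "n21", "n22", "w1", "w2")
  dimnames(A) <- list(nm, nm)
  with(u, {
    # stage-promoter occupancy block
    A["P10", "P10"] <- -(l1 + k1); A["P10", "P11"] <- g1
    A["P10", c("P20", "P21", "P22")] <- k2
    A["P11", "P10"] <- l1; A["P11", "P11"] <- -(g1 + k1)
    A["P20", c("P10", "P11")] <- k1
    A["P20", "P20"] <- -(2 * l2 + k2); A["P20", "P21"] <- g2
    A["P21", "P20"] <- 2 * l2; A["P21", "P21"] <- -(l2 + g2 + k2)
    A["P21", "P22"] <- 2 * g2
    A["P22", "P21"] <- l2; A["P22", "P22"] <- -(2 * g2 + k2)
    # promoter-resolved first moments (division halves the mean: kappa2/2)
    A["n10", c("n20", "n21", "n22")] <- k2 / 2
    A["n10", "n10"] <- -(d1 + l1 + k1); A["n10", "n11"] <- g1
    A["n11", "n10"] <- l1; A["n11", "n11"] <- -(d1 + g1 + k1)
    A["n11", "P11"] <- v1
    A["n20", c("n10", "n11")] <- k1
    A["n20", "n20"] <- -(d2 + 2 * l2 + k2); A["n20", "n21"] <- g2
    A["n21", "n20"] <- 2 * l2; A["n21", "n21"] <- -(d2 + l2 + g2 + k2)
    A["n21", "n22"] <- 2 * g2; A["n21", "P21"] <- v2
    A["n22", "n21"] <- l2; A["n22", "n22"] <- -(d2 + 2 * g2 + k2)
    A["n22", "P22"] <- 2 * v2
    # stage-partitioned second moments (binomial partition: E[M^2] -> w/4 + n/4)
    A["w1", "w1"] <- -(2 * d1 + k1); A["w1", "w2"] <- k2 / 4
    A["w1", c("n10", "n11")] <- d1
    A["w1", c("n20", "n21", "n22")] <- k2 / 4
    A["w1", "n11"] <- A["w1", "n11"] + 2 * v1
    A["w1", "P11"] <- v1
    A["w2", "w1"] <- k1; A["w2", "w2"] <- -(2 * d2 + k2)
    A["w2", c("n20", "n21", "n22")] <- d2
    A["w2", "n21"] <- A["w2", "n21"] + 2 * v2
    A["w2", "n22"] <- A["w2", "n22"] + 4 * v2
    A["w2", "P21"] <- v2
    A["w2", "P22"] <- A["w2", "P22"] + 2 * v2
    A
  })
}

#' Cell-cycle stage occupancy probabilities over time
#'
#' For a population synchronized at the start of S1, the probability of
#' residing in S1 at time `t` is
#' `P1(t) = kappa2/(kappa1+kappa2) + kappa1/(kappa1+kappa2) * exp(-(kappa1+kappa2) t)`
#' and `P2(t) = 1 - P1(t)`.
#'
#' @param t Non-negative time(s) in hours.
#' @param cycle A [cell_cycle_rates()] object.
#' @return A tibble with columns `t`, `P1`, `P2`.
#' @export
stage_probabilities <- function(t, cycle) {
  stopifnot(inherits(cycle, "cell_cycle_rates"))
  if (any(t < 0)) abort("t must be non-negative")
  ks <- cycle$kappa1 + cycle$kappa2
  P1 <- cycle$kappa2 / ks + cycle$kappa1 / ks * exp(-ks * t)
  tibble(t = t, P1 = P1, P2 = 1 - P1)
}

#' Moment dynamics from a synchronized start
#'
#' Solves the coupled linear systems for the joint stage-promoter
#' probabilities, the stage-partitioned first moments and the second
#' moments, starting from a population synchronized at the beginning of S1
#' with the promoter OFF and no (counted) transcripts. The combined system
#' is linear with constant coefficients and is solved exactly via the matrix
#' exponential at each requested time.
#'
#' Columns: occupancies `P10, P11, P20, P21, P22, P1, P2`; stage-partitioned
#' moments `n1, n2` (first) and `omega1, omega2` (second); stage-conditioned
#' moments `m1 = n1/P1`, `m2 = n2/P2`, `mu1 = omega1/P1`, `mu2 = omega2/P2`;
#' population moments `m = n1 + n2` and `mu = omega1 + omega2`. At `t = 0`
#' the S2 conditionals are undefined (`P2(0) = 0`) and reported as `NA`.
#'
#' @param params A [model_params()] object.
#' @param times Increasing non-negative time grid (hours).
#' @return A tibble with one row per time point.
#' @examples
#' p <- model_params(stage_kinetics(1, 2, 5, 1), cycle = cell_cycle_rates(0.5, 0.5))
#' moment_dynamics(p, times = c(0, 1, 5, 50))
#' @export
moment_dynamics <- function(params, times) {
  if (any(times < 0)) abort("times must be non-negative")
  if (is.unsorted(times)) abort("times must be increasing")
  A <- moment_matrix(params)
  x0 <- c(1, rep(0, 11))
  sol <- vapply(times, function(t) {
    as.numeric(Matrix::expm(A * t) %*% x0)
  }, numeric(12))
  rownames(sol) <- c("P10", "P11", "P20", "P21", "P22",
                     "n10", "n11", "n20", "n21", "n22", "omega1", "omega2")
  out <- as_tibble(t(sol))
  out <- dplyr::mutate(out,
    t = times,
    P1 = .data$P10 + .data$P11,
    P2 = .data$P20 + .data$P21 + .data$P22,
    n1 = .data$n10 + .data$n11,
    n2 = .data$n20 + .data$n21 + .data$n22,
    m = .data$n1 + .data$n2,
    mu = .data$omega1 + .data$omega2,
    m1 = .data$n1 / .data$P1,
    m2 = ifelse(.data$P2 > 0, .data$n2 / .data$P2, NA_real_),
    mu1 = .data$omega1 / .data$P1,
    mu2 = ifelse(.data$P2 > 0, .data$omega2 / .data$P2, NA_real_)
  )
  dplyr::select(out, "t", "P10", "P11", "P20", "P21", "P22", "P1", "P2",
                "n10", "n11", "n20", "n21", "n22", "n1", "n2",
                "omega1", "omega2", "m1", "m2", "mu1", "mu2", "m", "mu")
}

#' @describeIn moment_dynamics Occupancy probabilities of the five joint
#'   stage-promoter states only.
#' @export
promoter_occupancy <- function(params, times) {
  dplyr::select(moment_dynamics(params, times),
                "t", "P10", "P11", "P20", "P21", "P22", "P1", "P2")
}
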