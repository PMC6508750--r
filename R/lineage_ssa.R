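# Exact stochastic simulation of a single-cell lineage.

#' Simulate a single-cell lineage
#'
#' Gillespie simulation of the telegraph model coupled to the two-stage cell
#' cycle, following one cell through successive divisions (one daughter is
#' kept at random; binomial thinning with keep-probability 1/2 of the
#' transcript count implements the even partitioning for the followed
#' daughter). Propensities per stage: activation `lambda * (copies - I)`,
#' inactivation `gamma * I`, synthesis `nu * I`, degradation `delta * M`,
#' and the stage transition (`kappa1` or `kappa2`). Entering S2 both copies
#' start OFF; after division the single copy starts OFF.
#'
#' Randomness comes from R's RNG: call `set.seed()` (or pass `seed`) for
#' byte-reproducible trajectories.
#'
#' @param params A [model_params()] object.
#' @param t_max Simulated time horizon in hours (the run also stops after
#'   `max_cycles` completed cycles).
#' @param seed Optional integer seed, applied via `set.seed()`.
#' @param max_cycles Cap on completed division cycles.
#' @param record_events If `TRUE`, keep the full event path (class of output
#'   gains an `events` tibble with the post-event state and the
#'   propensity-scaled waiting time of each jump, which is Exp(1) for an
#'   exact simulator).
#' @return A list of class `telecycle_ssa` with `cycles` (per-cycle tibble
#'   of stage-resolved occupation times and time-integrals of `M` and
#'   `M^2`, plus counts just before/after each division), `n_cycles`,
#'   `t_end`, and optionally `events`.
#' @examples
#' p <- model_params(stage_kinetics(1, 2, 5, 1), cycle = cell_cycle_rates(0.5, 0.5))
#' sim <- simulate_lineage(p, t_max = 500, seed = 1)
#' estimate_stage_moments(sim)
#' @export
simulate_lineage <- function(params, t_max, seed = NULL,
                             max_cycles = .Machine$integer.max,
                             record_events = FALSE) {
  stopifnot(inherits(params, "model_params"), t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- unpack(params)
  res <- .simulate_lineage_cpp(u$l1, u$g1, u$v1, u$d1,
                               u$l2, u$g2, u$v2, u$d2,
                               u$k1, u$k2, t_max, as.integer(max_cycles),
                               record_events)
  res$cycles <- as_tibble(res$cycles)
  if (record_events) res$events <- as_tibble(res$events)
  res$params <- params
  class(res) <- "telecycle_ssa"
  res
}

#' @export
print.telecycle_ssa <- function(x, ...) {
  cat(sprintf("<telecycle_ssa> %d completed cycles over %.4g h\n",
              x$n_cycles, x$t_end))
  invisible(x)
}

#' Stage-conditioned moment estimates from a lineage simulation
#'
#' Time-weighted estimators of the stationary stage-conditioned mean, second
#' moment, variance, noise (`eta2`) and noise strength (`phi`), per stage and
#' overall, with Monte-Carlo standard errors from batch means over completed
#' cycles (cycles are grouped into `n_batches` consecutive batches; each
#' batch yields one estimate of every quantity and the SE is the batch
#' standard deviation over `sqrt(n_batches)`).
#'
#' @param sim A `telecycle_ssa` object from [simulate_lineage()].
#' @param burn_in_cycles Completed cycles discarded before estimation
#'   (transient from the synchronized start). Default 20, reduced only if
#'   fewer cycles are available is an error instead.
#' @param n_batches Number of batches for the SE (default 20, at least 5
#'   cycles each is required).
#' @return A tibble with one row per quantity and stage (`stage` in
#'   `"S1"`, `"S2"`, `"all"`): columns `stage`, `quantity`, `estimate`,
#'   `se`, plus attributes-free columns `n_cycles` and `occupancy`.
#' @export
estimate_stage_moments <- function(sim, burn_in_cycles = 20, n_batches = 20) {
  stopifnot(inherits(sim, "telecycle_ssa"))
  cyc <- sim$cycles
  if (nrow(cyc) < burn_in_cycles + 10) {
    abort(sprintf("only %d completed cycles; need at least burn_in + 10",
                  nrow(cyc)))
  }
  cyc <- cyc[-seq_len(burn_in_cycles), , drop = FALSE]
  n <- nrow(cyc)
  n_batches <- max(2L, min(n_batches, n %/% 5L))
  batch <- cut(seq_len(n), n_batches, labels = FALSE)

  batch_stats <- function(d) {
    t1 <- sum(d$time_s1); t2 <- sum(d$time_s2); tt <- t1 + t2
    m1 <- sum(d$int_m_s1) / t1
    m2 <- sum(d$int_m_s2) / t2
    mu1 <- sum(d$int_m2_s1) / t1
    mu2 <- sum(d$int_m2_s2) / t2
    m <- (sum(d$int_m_s1) + sum(d$int_m_s2)) / tt
    mu <- (sum(d$int_m2_s1) + sum(d$int_m2_s2)) / tt
    c(m1 = m1, m2 = m2, m = m, mu1 = mu1, mu2 = mu2, mu = mu,
      var1 = mu1 - m1^2, var2 = mu2 - m2^2, var = mu - m^2,
      phi1 = (mu1 - m1^2) / m1, phi2 = (mu2 - m2^2) / m2,
      phi = (mu - m^2) / m,
      eta2_1 = (mu1 - m1^2) / m1^2, eta2_2 = (mu2 - m2^2) / m2^2,
      eta2 = (mu - m^2) / m^2, occ_s1 = t1 / tt)
  }
  overall <- batch_stats(cyc)
  per_batch <- vapply(split(cyc, batch), batch_stats,
                      numeric(length(overall)))
  se <- apply(per_batch, 1, stats::sd) / sqrt(n_batches)

  tibble(
    quantity = c(rep(c("mean", "second_moment", "variance", "phi", "eta2"),
                     each = 3), "occupancy_s1"),
    stage = c(rep(c("S1", "S2", "all"), 5), "all"),
    estimate = unname(overall[c("m1", "m2", "m", "mu1", "mu2", "mu",
                                "var1", "var2", "var", "phi1", "phi2", "phi",
                                "eta2_1", "eta2_2", "eta2", "occ_s1")]),
    se = unname(se[c("m1", "m2", "m", "mu1", "mu2", "mu",
                     "var1", "var2", "var", "phi1", "phi2", "phi",
                     "eta2_1", "eta2_2", "eta2", "occ_s1")]),
    n_cycles = n, n_batches = n_batches
  )
}

# pull one estimate +/- se from the tidy estimate table
moment_estimate <- function(est, quantity, stage) {
  row <- est[est$quantity == quantity & est$stage == stage, ]
  if (nrow(row) != 1) abort("no such estimate")
  row
}
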