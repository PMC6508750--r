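# Shared fixtures: parameter sets used across the suite.

# moderate-mean set used for oracle cross-checks
baseline_params <- function() {
  model_params(stage_kinetics(1, 2, 5, 1),
               cycle = cell_cycle_rates(0.5, 0.5))
}

# mouse ES cell telegraph kinetics (rates hr^-1; nu = 1.89 min^-1)
mesc_kinetics <- function() {
  stage_kinetics(lambda = 0.5556, gamma = 1.0714, nu = 1.89 * 60,
                 delta = 0.14)
}

# mean S1 = 560 min, mean S2 = 220 min
mesc_cycle <- function() cell_cycle_rates(60 / 560, 60 / 220)

# Oct4 parameter set: shared synthesis/degradation, stage-specific activation
oct4_params <- function(nu = 1) {
  model_params(
    stage_kinetics(lambda = 0.5556, gamma = 1.0714, nu = nu, delta = 17.14),
    stage_kinetics(lambda = 0.3468, gamma = 1.0714, nu = nu, delta = 17.14),
    cycle = cell_cycle_rates(0.1071, 0.2727)
  )
}

# log-uniform random rate in [lo, hi]
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

random_params <- function() {
  model_params(
    stage_kinetics(runif_log(1, 0.05, 5), runif_log(1, 0.05, 5),
                   runif_log(1, 0.5, 50), runif_log(1, 0.05, 5)),
    stage_kinetics(runif_log(1, 0.05, 5), runif_log(1, 0.05, 5),
                   runif_log(1, 0.5, 50), runif_log(1, 0.05, 5)),
    cycle = cell_cycle_rates(runif_log(1, 0.02, 2), runif_log(1, 0.02, 2))
  )
}

random_shared_params <- function() {
  k <- stage_kinetics(runif_log(1, 0.05, 5), runif_log(1, 0.05, 5),
                      runif_log(1, 0.5, 50), runif_log(1, 0.05, 5))
  model_params(k, cycle = cell_cycle_rates(runif_log(1, 0.02, 2),
                                           runif_log(1, 0.02, 2)))
}

# parameter sets spanning slow and fast cycling, all with moderate means,
# used for the closed-form vs master-equation vs simulation comparisons
oracle_panel <- function() {
  list(
    baseline = baseline_params(),
    asymmetric = model_params(stage_kinetics(0.8, 1.5, 6, 0.9),
                              stage_kinetics(1.7, 0.6, 3.2, 1.4),
                              cycle = cell_cycle_rates(0.35, 0.9)),
    slow_cycling = model_params(stage_kinetics(1, 1, 8, 1),
                                cycle = cell_cycle_rates(0.05, 0.08)),
    fast_cycling = model_params(stage_kinetics(1.2, 0.8, 6, 1),
                                cycle = cell_cycle_rates(5, 8)),
    bursty = model_params(stage_kinetics(0.3, 3, 20, 2),
                          cycle = cell_cycle_rates(0.4, 1.2))
  )
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
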