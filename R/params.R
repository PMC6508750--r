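#' Telegraph kinetics of one cell-cycle stage
#'
#' Bundles the four first-order rate constants of the two-state (telegraph)
#' promoter model for a single cell-cycle stage: the promoter switches
#' OFF -> ON at rate `lambda` and ON -> OFF at rate `gamma`; each active gene
#' copy synthesises mRNA at rate `nu`; each transcript degrades at rate
#' `delta`. All rates are per hour.
#'
#' @param lambda Promoter activation rate (hr^-1), per gene copy.
#' @param gamma Promoter inactivation rate (hr^-1), per gene copy.
#' @param nu mRNA synthesis rate while active (hr^-1), per gene copy.
#' @param delta mRNA degradation rate (hr^-1), per molecule.
#' @return An object of class `stage_kinetics` (a named list of four rates).
#' @examples
#' stage_kinetics(lambda = 0.5556, gamma = 1.0714, nu = 113.4, delta = 0.14)
#' @export
stage_kinetics <- function(lambda, gamma, nu, delta) {
  rates <- c(lambda = lambda, gamma = gamma, nu = nu, delta = delta)
  check_positive_rates(rates, "stage_kinetics")
  structure(as.list(rates), class = "stage_kinetics")
}

#' Cell-cycle stage transition rates
#'
#' The cell cycle is split at the instant the gene of interest is duplicated:
#' stage S1 (one gene copy) lasts an exponential time with rate `kappa1`;
#' stage S2 (two copies) lasts an exponential time with rate `kappa2`, at the
#' end of which the cell divides and each mRNA molecule is kept with
#' probability 1/2.
#'
#' @param kappa1 S1 -> S2 (gene duplication) rate, hr^-1.
#' @param kappa2 S2 -> division rate, hr^-1.
#' @return An object of class `cell_cycle_rates`.
#' @examples
#' cell_cycle_rates(kappa1 = 60 / 560, kappa2 = 60 / 220)
#' @export
cell_cycle_rates <- function(kappa1, kappa2) {
  rates <- c(kappa1 = kappa1, kappa2 = kappa2)
  check_positive_rates(rates, "cell_cycle_rates")
  structure(as.list(rates), class = "cell_cycle_rates")
}

#' Full model parameter set
#'
#' Combines the telegraph kinetics of both cell-cycle stages with the stage
#' transition rates. Construction validates positivity of every rate and of
#' the two denominators `2(delta1+kappa1)(delta2+kappa2) - kappa1*kappa2` and
#' `4(kappa1+2*delta1)(kappa2+2*delta2) - kappa1*kappa2` that appear in the
#' stationary moment formulas (both are provably positive for positive rates;
#' the assertion guards against degenerate numeric input).
#'
#' @param stage1,stage2 [stage_kinetics()] objects for S1 and S2. If `stage2`
#'   is missing, the S1 kinetics are shared by both stages (the
#'   constant-kinetics constraint used throughout the fold-change theory).
#' @param cycle A [cell_cycle_rates()] object.
#' @return An object of class `model_params` with elements `stage1`, `stage2`,
#'   `cycle`.
#' @examples
#' p <- model_params(
#'   stage_kinetics(1, 2, 5, 1),
#'   cycle = cell_cycle_rates(0.5, 0.5)
#' )
#' fold_change(p)
#' @export
model_params <- function(stage1, stage2 = stage1, cycle) {
  stopifnot(inherits(stage1, "stage_kinetics"), inherits(stage2, "stage_kinetics"),
            inherits(cycle, "cell_cycle_rates"))
  p <- structure(list(stage1 = stage1, stage2 = stage2, cycle = cycle),
                 class = "model_params")
  with(unpack(p), {
    if (2 * (d1 + k1) * (d2 + k2) - k1 * k2 <= 0 ||
        4 * (k1 + 2 * d1) * (k2 + 2 * d2) - k1 * k2 <= 0) {
      abort("degenerate parameter set: moment denominators are not positive")
    }
  })
  p
}

check_positive_rates <- function(rates, what) {
  bad <- !is.finite(rates) | rates <= 0
  if (any(bad)) {
    abort(sprintf("%s: rate(s) %s must be strictly positive and finite",
                  what, paste(names(rates)[bad], collapse = ", ")))
  }
  invisible(rates)
}

# flatten a model_params into the ten scalars used by every formula
unpack <- function(params) {
  list(
    l1 = params$stage1$lambda, g1 = params$stage1$gamma,
    v1 = params$stage1$nu,     d1 = params$stage1$delta,
    l2 = params$stage2$lambda, g2 = params$stage2$gamma,
    v2 = params$stage2$nu,     d2 = params$stage2$delta,
    k1 = params$cycle$kappa1,  k2 = params$cycle$kappa2
  )
}

#' @export
print.model_params <- function(x, ...) {
  u <- unpack(x)
  cat("<model_params> rates in hr^-1\n")
  cat(sprintf("  S1: lambda=%g gamma=%g nu=%g delta=%g\n", u$l1, u$g1, u$v1, u$d1))
  cat(sprintf("  S2: lambda=%g gamma=%g nu=%g delta=%g\n", u$l2, u$g2, u$v2, u$d2))
  cat(sprintf("  cycle: kappa1=%g kappa2=%g (mean durations %.3g h, %.3g h)\n",
              u$k1, u$k2, 1 / u$k1, 1 / u$k2))
  invisible(x)
}

#' @export
print.stage_kinetics <- function(x, ...) {
  cat(sprintf("<stage_kinetics> lambda=%g gamma=%g nu=%g delta=%g (hr^-1)\n",
              x$lambda, x$gamma, x$nu, x$delta))
  invisible(x)
}

#' @export
print.cell_cycle_rates <- function(x, ...) {
  cat(sprintf("<cell_cycle_rates> kappa1=%g kappa2=%g (hr^-1)\n",
              x$kappa1, x$kappa2))
  invisible(x)
}

#' @export
as_tibble.model_params <- function(x, ...) {
  as_tibble(unpack_named(x))
}

unpack_named <- function(params) {
  u <- unpack(params)
  list(lambda1 = u$l1, gamma1 = u$g1, nu1 = u$v1, delta1 = u$d1,
       lambda2 = u$l2, gamma2 = u$g2, nu2 = u$v2, delta2 = u$d2,
       kappa1 = u$k1, kappa2 = u$k2)
}

#' Convert a rate between time units
#'
#' The canonical internal unit is per hour; published rate constants are often
#' quoted per minute. Conversion is exact (`per_minute` values are multiplied
#' by 60).
#'
#' @param x Numeric rate value(s).
#' @param from Unit tag of `x`: `"per_hour"` or `"per_minute"`.
#' @return The rate(s) in hr^-1.
#' @examples
#' convert_rate(1.89, "per_minute") # 113.4 hr^-1
#' @export
convert_rate <- function(x, from = c("per_hour", "per_minute")) {
  from <- arg_match(from)
  switch(from, per_hour = x, per_minute = x * 60)
}

#' Read a model parameter set from a YAML or JSON-style config
#'
#' Expects keys `stage1`, `stage2` (each with `lambda`, `gamma`, `nu`,
#' `delta`), `cycle` (`kappa1`, `kappa2`), and an optional
#' `units: {rates: per_hour|per_minute}` block applied to every rate. If
#' `stage2` is omitted the S1 kinetics are shared by both stages.
#'
#' @param path Path to a YAML file (JSON is valid YAML).
#' @return A [model_params()] object with all rates in hr^-1.
#' @export
read_model_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  unit <- cfg$units$rates %||% "per_hour"
  if (!unit %in% c("per_hour", "per_minute")) {
    abort(sprintf("units$rates: unknown unit tag '%s'", unit))
  }
  grab <- function(block, keys, where) {
    vals <- lapply(keys, function(k) {
      v <- block[[k]]
      if (is.null(v)) abort(sprintf("config field '%s$%s' is missing", where, k))
      convert_rate(as.numeric(v), unit)
    })
    setNames(vals, keys)
  }
  s1 <- grab(cfg$stage1, c("lambda", "gamma", "nu", "delta"), "stage1")
  s2 <- if (is.null(cfg$stage2)) s1 else
    grab(cfg$stage2, c("lambda", "gamma", "nu", "delta"), "stage2")
  cy <- grab(cfg$cycle, c("kappa1", "kappa2"), "cycle")
  model_params(do.call(stage_kinetics, s1), do.call(stage_kinetics, s2),
               cycle = do.call(cell_cycle_rates, cy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean duplication time of a single gene during genome replication
#'
#' With a genome of `genome_bp` base pairs carrying `n_genes` genes replicated
#' at `replication_rate` base pairs per second, the average single-gene
#' duplication time is `(genome_bp / n_genes) / replication_rate` seconds.
#' This is the back-of-envelope argument for treating gene duplication as
#' instantaneous relative to cell-cycle stage durations.
#'
#' @param genome_bp Genome size in base pairs.
#' @param n_genes Number of genes.
#' @param replication_rate Replication speed in bp per second.
#' @return Mean duplication time in seconds.
#' @examples
#' mean_gene_duplication_time(4.64e6, 4375, 650) # ~1.63 s
#' @export
mean_gene_duplication_time <- function(genome_bp, n_genes, replication_rate) {
  if (genome_bp <= 0 || n_genes <= 0 || replication_rate <= 0) {
    abort("genome_bp, n_genes and replication_rate must all be positive")
  }
  (genome_bp / n_genes) / replication_rate
}
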