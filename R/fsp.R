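# Truncated master-equation solver (finite state projection).
#
# Brute-force companion to the closed forms: the joint distribution over
# (stage, active copies, mRNA count <= N) is evolved or solved at
# stationarity directly from the master equations, including the binomial
# redistribution of transcripts at division. Moments computed here by
# summation never touch the analytical formulas, so the two routes
# adjudicate each other.

fsp_index <- function(N) {
  nm <- N + 1
  list(
    nm = nm, S = 5 * nm,
    s1 = function(i, m) i * nm + m + 1,          # i in 0:1
    s2 = function(i, m) 2 * nm + i * nm + m + 1  # i in 0:2
  )
}

#' Truncation bound suggested by the closed-form moments
#'
#' Standard finite-state-projection sizing: `ceil(mean + 10 sd)` of the
#' larger-mean stage, raised to the fully-active quasi-stationary mean plus
#' ten Poisson standard deviations, bounded below by 10. Only the truncation
#' size uses the closed forms; the solved distribution itself never does.
#'
#' @param params A [model_params()] object.
#' @return An integer truncation bound `N`.
#' @export
fsp_truncation_hint <- function(params) {
  s <- steady_state(params)
  u <- unpack(params)
  # fully-active quasi-stationary mean: Poisson-like ceiling for the
  # conditional branches that the mixture sd under-represents
  q <- max(u$v1 / u$d1, 2 * u$v2 / u$d2)
  top <- max(s$m1_star + 10 * sqrt(max(s$mu1_star - s$m1_star^2, 0)),
             s$m2_star + 10 * sqrt(max(s$mu2_star - s$m2_star^2, 0)),
             q + 10 * sqrt(q))
  max(10L, as.integer(ceiling(top)))
}

#' Generator of the truncated master equation
#'
#' Builds the sparse generator over the `5 * (N + 1)` joint states
#' (S1: promoter OFF/ON; S2: 0, 1 or 2 active copies; mRNA count `0..N`).
#' Reactions: promoter switching (with copy-number multiplicities in S2),
#' synthesis (`nu1` per active copy in S1, `nu2 * i` in S2), first-order
#' degradation, gene duplication S1 -> S2 at `kappa1` (both copies start
#' OFF), and division S2 -> S1 at `kappa2` with binomial `(n, 1/2)`
#' redistribution of the `n` transcripts (promoter OFF after division).
#' Truncation is absorbing: synthesis out of `m = N` leaks probability, so
#' total mass under-counts by the projection error.
#'
#' @param params A [model_params()] object.
#' @param N Truncation bound (max mRNA count), `>= 1`.
#' @return A sparse `dgCMatrix` `A` such that `dp/dt = A p`, with the state
#'   layout stored in attributes `N` and `layout`.
#' @export
fsp_generator <- function(params, N) {
  stopifnot(N >= 1)
  u <- unpack(params)
  ix <- fsp_index(N)
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  put <- function(f, t, r) {
    from <<- c(from, f); to <<- c(to, t)
    rate <<- c(rate, rep_len(r, length(f)))
  }
  ms <- 0:N
  with(u, {
    # promoter switching
    put(ix$s1(0, ms), ix$s1(1, ms), l1)
    put(ix$s1(1, ms), ix$s1(0, ms), g1)
    put(ix$s2(0, ms), ix$s2(1, ms), 2 * l2)
    put(ix$s2(1, ms), ix$s2(2, ms), l2)
    put(ix$s2(1, ms), ix$s2(0, ms), g2)
    put(ix$s2(2, ms), ix$s2(1, ms), 2 * g2)
    # synthesis (transition dropped at m = N: absorbing truncation)
    if (N >= 1) {
      mlo <- 0:(N - 1)
      put(ix$s1(1, mlo), ix$s1(1, mlo + 1), v1)
      put(ix$s2(1, mlo), ix$s2(1, mlo + 1), v2)
      put(ix$s2(2, mlo), ix$s2(2, mlo + 1), 2 * v2)
    }
    # degradation
    if (N >= 1) {
      mhi <- 1:N
      put(ix$s1(0, mhi), ix$s1(0, mhi - 1), mhi * d1)
      put(ix$s1(1, mhi), ix$s1(1, mhi - 1), mhi * d1)
      for (i in 0:2) put(ix$s2(i, mhi), ix$s2(i, mhi - 1), mhi * d2)
    }
    # gene duplication: S1 (i, m) -> S2 (0, m); transcription re-starts OFF
    for (i in 0:1) put(ix$s1(i, ms), ix$s2(0, ms), k1)
    # division: S2 (i, n) -> S1 (0, Binomial(n, 1/2))
    for (n in ms) {
      w <- dbinom(0:n, n, 0.5)
      for (i in 0:2) put(rep(ix$s2(i, n), n + 1), ix$s1(0, 0:n), k2 * w)
    }
  })
  A <- Matrix::sparseMatrix(i = to, j = from, x = rate,
                            dims = c(ix$S, ix$S))
  # diagonal carries the FULL outflow incl. the truncated synthesis reaction
  d <- rep(0, ix$S)
  d[ix$s1(0, ms)] <- u$l1 + u$k1 + ms * u$d1
  d[ix$s1(1, ms)] <- u$g1 + u$k1 + ms * u$d1 + u$v1
  d[ix$s2(0, ms)] <- 2 * u$l2 + u$k2 + ms * u$d2
  d[ix$s2(1, ms)] <- u$l2 + u$g2 + u$k2 + ms * u$d2 + u$v2
  d[ix$s2(2, ms)] <- 2 * u$g2 + u$k2 + ms * u$d2 + 2 * u$v2
  A <- A - Matrix::Diagonal(x = d)
  attr(A, "N") <- N
  A
}

fsp_state_table <- function(N) {
  nm <- N + 1
  tibble(
    stage = rep(c(1L, 1L, 2L, 2L, 2L), each = nm),
    i = rep(c(0L, 1L, 0L, 1L, 2L), each = nm),
    m = rep(0:N, 5)
  )
}

fsp_summarise <- function(p, N, t = NA_real_) {
  st <- fsp_state_table(N)
  p <- pmax(p, 0)
  in1 <- st$stage == 1L
  P1 <- sum(p[in1]); P2 <- sum(p[!in1])
  m1 <- sum(st$m[in1] * p[in1]) / P1
  m2 <- sum(st$m[!in1] * p[!in1]) / P2
  mu1 <- sum(st$m[in1]^2 * p[in1]) / P1
  mu2 <- sum(st$m[!in1]^2 * p[!in1]) / P2
  mass <- P1 + P2
  tibble(
    t = t, mass = mass, tail_mass = sum(p[st$m > 0.9 * N]),
    P1 = P1 / mass, P2 = P2 / mass,
    m1 = m1, m2 = m2, mu1 = mu1, mu2 = mu2,
    m = (sum(st$m * p)) / mass, mu = (sum(st$m^2 * p)) / mass,
    p22_given_s2 = sum(p[st$stage == 2L & st$i == 2L]) / P2
  )
}

#' Evolve the truncated master equation
#'
#' Integrates `dp/dt = A p` from the synchronized initial condition (all
#' mass on S1, promoter OFF, zero transcripts) and reports stage-conditioned
#' moments at each requested time. Probability is conserved up to the
#' truncation (projection) error, which is monitored as `1 - mass`.
#'
#' @param params A [model_params()] object.
#' @param times Increasing non-negative output times (hours).
#' @param N Truncation bound; default [fsp_truncation_hint()].
#' @param tail_tol Maximum tolerated probability loss; exceeded -> error
#'   recommending a larger `N`.
#' @param distributions If `TRUE`, also return the full joint distributions.
#' @return A tibble with one row per time (`t`, `mass`, `tail_mass`, `P1`,
#'   `P2`, conditioned moments `m1`, `m2`, `mu1`, `mu2`, population `m`,
#'   `mu`, `p22_given_s2`). With `distributions = TRUE`, a list with fields
#'   `moments` and `prob` (matrix of state probabilities, one column per
#'   time, rows in the layout of `fsp_generator`).
#' @export
fsp_evolve <- function(params, times, N = fsp_truncation_hint(params),
                       tail_tol = 1e-8, distributions = FALSE) {
  if (any(times < 0) || is.unsorted(times)) {
    abort("times must be non-negative and increasing")
  }
  A <- fsp_generator(params, N)
  p0 <- numeric(5 * (N + 1)); p0[1] <- 1
  t_ode <- unique(c(0, times))
  sol <- deSolve::ode(
    y = p0, times = t_ode,
    func = function(t, y, parms) list(as.numeric(A %*% y)),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  keep <- match(times, t_ode)
  prob <- t(sol[keep, -1, drop = FALSE])
  mom <- dplyr::bind_rows(lapply(seq_along(times), function(j) {
    fsp_summarise(prob[, j], N, t = times[j])
  }))
  if (any(1 - mom$mass > tail_tol)) {
    abort(sprintf(
      "truncation loss %.3g exceeds tail_tol = %g; increase N (currently %d)",
      max(1 - mom$mass), tail_tol, N))
  }
  if (distributions) list(moments = mom, prob = prob) else mom
}

#' Stationary distribution of the truncated master equation
#'
#' Solves `A p = 0` with unit total mass. The default sparse nullspace solve
#' (replace one balance equation by the normalization) is exact at the level
#' of the truncated system; long-time integration is available as a
#' cross-check.
#'
#' @inheritParams fsp_evolve
#' @param method `"nullspace"` (default) or `"integrate"` (run the dynamics
#'   to `t = 50 / min(kappa1, kappa2, delta1, delta2)`).
#' @return As [fsp_evolve()] for a single (stationary) row; with
#'   `distributions = TRUE`, a list with `moments` and the probability
#'   vector `prob`.
#' @examples
#' p <- model_params(stage_kinetics(1, 2, 5, 1), cycle = cell_cycle_rates(0.5, 0.5))
#' fsp_stationary(p)
#' @export
fsp_stationary <- function(params, N = fsp_truncation_hint(params),
                           method = c("nullspace", "integrate"),
                           tail_tol = 1e-8, distributions = FALSE) {
  method <- arg_match(method)
  if (method == "integrate") {
    u <- unpack(params)
    t_end <- 50 / min(u$k1, u$k2, u$d1, u$d2)
    res <- fsp_evolve(params, times = t_end, N = N, tail_tol = tail_tol,
                      distributions = distributions)
    if (distributions) {
      return(list(moments = dplyr::mutate(res$moments, t = Inf),
                  prob = as.numeric(res$prob)))
    }
    return(dplyr::mutate(res, t = Inf))
  }
  A <- fsp_generator(params, N)
  S <- nrow(A)
  M <- rbind(A[-S, , drop = FALSE], Matrix::sparseMatrix(
    i = rep(1, S), j = seq_len(S), x = 1, dims = c(1, S)))
  p <- as.numeric(Matrix::solve(M, c(rep(0, S - 1), 1)))
  if (min(p) < -1e-9) {
    abort("stationary solve produced significant negative mass; increase N")
  }
  mom <- fsp_summarise(p, N, t = Inf)
  if (1 - mom$mass > tail_tol) {
    abort(sprintf("truncation loss %.3g exceeds tail_tol = %g; increase N",
                  1 - mom$mass, tail_tol))
  }
  if (distributions) list(moments = mom, prob = p) else mom
}
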