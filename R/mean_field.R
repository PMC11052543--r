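# Well-mixed mean-field AMHa dynamics: ODE right-hand side, integration,
# steady state.

#' Mean-field AMHa derivatives
#'
#' Right-hand side of the well-mixed three-compartment system. Each flow
#' X -> Y equals `X * (alpha_XY + sum_Z beta_XY^Z g(Z))` per year, with all
#' six ordered transitions (including the direct A <-> H superinfection
#' channels). Under the default per-capita convention `g(Z) = Z / N`, so
#' trajectories of fractions are invariant to N; under `"per_count"`
#' `g(Z) = Z`, matching a network simulation on a dense graph where beta
#' multiplies integer neighbour counts.
#'
#' @param state numeric vector `c(A, M, H)` (counts or fractions).
#' @param params an [amha_parameters()] (rates per reference period; they
#'   are converted to per-year internally).
#' @param density `"per_capita"` (default) or `"per_count"`.
#' @return named vector `c(A, M, H)` of time derivatives per year; they
#'   sum to zero by construction.
#' @export
amha_derivatives <- function(state, params,
                             density = c("per_capita", "per_count")) {
  density <- match.arg(density)
  s <- AMHA_STATES
  state <- setNames(as.numeric(state), s)
  stopifnot(all(state >= -1e-12))
  N <- sum(state)
  ry <- rates_per_year(params)
  g <- if (density == "per_capita" && N > 0) state / N else state
  d <- setNames(numeric(3), s)
  for (from in s) for (to in setdiff(s, from)) {
    flow <- state[from] * (ry$alpha[from, to] + sum(ry$beta[from, to, ] * g))
    d[from] <- d[from] - flow
    d[to] <- d[to] + flow
  }
  d
}

# one RK4 step
.rk4_step <- function(y, h, f) {
  k1 <- f(y)
  k2 <- f(y + h / 2 * k1)
  k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Integrate the mean-field AMHa system
#'
#' Explicit integration of [amha_derivatives()]. The default is classical
#' fixed-step RK4 (bit-reproducible); `method = "adaptive"` uses embedded
#' Runge-Kutta-Fehlberg 4(5) with step-doubling on the error estimate.
#' Tiny negative components (within `tol`) are projected back to zero and
#' the state renormalized to conserve the total; a violation beyond `tol`
#' aborts with a step-size error.
#'
#' @param initial numeric `c(A, M, H)` at time 0.
#' @param params an [amha_parameters()].
#' @param horizon_years integration horizon (> 0).
#' @param step output (and RK4 internal) step in years.
#' @param method `"rk4"` or `"adaptive"`.
#' @param density see [amha_derivatives()].
#' @param tol positivity/conservation tolerance relative to N.
#' @return data.frame of class `amha_trajectory`: `time`, `A`, `M`, `H`.
#' @export
integrate_amha <- function(initial, params, horizon_years, step = 0.05,
                           method = c("rk4", "adaptive"),
                           density = c("per_capita", "per_count"),
                           tol = 1e-6) {
  method <- match.arg(method); density <- match.arg(density)
  stopifnot(horizon_years > 0, step > 0)
  s <- AMHA_STATES
  y <- setNames(as.numeric(initial), s)
  N <- sum(y)
  f <- function(y) amha_derivatives(y, params, density)
  times <- seq(0, horizon_years, by = step)
  if (tail(times, 1) < horizon_years) times <- c(times, horizon_years)
  out <- matrix(NA_real_, length(times), 3, dimnames = list(NULL, s))
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    h <- times[i] - times[i - 1]
    if (method == "rk4") {
      y <- .rk4_step(y, h, f)
    } else {
      y <- .rkf45_advance(y, h, f, tol * max(N, 1))
    }
    if (any(y < -tol * max(N, 1)))
      stop("negative compartment beyond tolerance; decrease the step size")
    y <- pmax(y, 0)
    y <- y * (N / sum(y))        # positivity projection conserving N
    out[i, ] <- y
  }
  traj <- data.frame(time = times, out)
  class(traj) <- c("amha_trajectory", "data.frame")
  traj
}

# advance one interval h with adaptive RKF45 substeps
.rkf45_advance <- function(y, h, f, atol) {
  t <- 0
  hs <- h
  while (t < h - 1e-12) {
    hs <- min(hs, h - t)
    res <- .rkf45_step(y, hs, f)
    err <- max(abs(res$err))
    if (err <= atol || hs < 1e-8) {
      y <- res$y
      t <- t + hs
      if (err < atol / 10) hs <- hs * 2
    } else {
      hs <- hs / 2
    }
  }
  y
}

# one embedded Fehlberg 4(5) step; returns 5th-order solution and error
.rkf45_step <- function(y, h, f) {
  k1 <- f(y)
  k2 <- f(y + h * k1 / 4)
  k3 <- f(y + h * (3 * k1 + 9 * k2) / 32)
  k4 <- f(y + h * (1932 * k1 - 7200 * k2 + 7296 * k3) / 2197)
  k5 <- f(y + h * (439 / 216 * k1 - 8 * k2 + 3680 / 513 * k3 - 845 / 4104 * k4))
  k6 <- f(y + h * (-8 / 27 * k1 + 2 * k2 - 3544 / 2565 * k3 +
                     1859 / 4104 * k4 - 11 / 40 * k5))
  y4 <- y + h * (25 / 216 * k1 + 1408 / 2565 * k3 + 2197 / 4104 * k4 - k5 / 5)
  y5 <- y + h * (16 / 135 * k1 + 6656 / 12825 * k3 + 28561 / 56430 * k4 -
                   9 / 50 * k5 + 2 / 55 * k6)
  list(y = y5, err = y5 - y4)
}

#' Mean-field steady state
#'
#' Integrates until the maximum derivative falls below `tol * N` per year
#' (or a horizon cap is hit, in which case the result is flagged as
#' unconverged).
#'
#' @param params an [amha_parameters()].
#' @param initial numeric `c(A, M, H)`.
#' @param tol convergence tolerance on max |d/dt| relative to N.
#' @param max_years horizon cap.
#' @param density,step,method passed to [integrate_amha()].
#' @return named vector `c(A, M, H)` with attributes `converged` (logical)
#'   and `years` (time used).
#' @export
steady_state_amha <- function(params, initial, tol = 1e-8, max_years = 2000,
                              density = c("per_capita", "per_count"),
                              step = 0.05, method = "rk4") {
  density <- match.arg(density)
  y <- setNames(as.numeric(initial), AMHA_STATES)
  N <- sum(y)
  t <- 0
  chunk <- 50
  repeat {
    d <- amha_derivatives(y, params, density)
    if (max(abs(d)) < tol * max(N, 1)) break
    if (t >= max_years) break
    traj <- integrate_amha(y, params, horizon_years = chunk, step = step,
                           method = method, density = density)
    y <- setNames(as.numeric(traj[nrow(traj), AMHA_STATES]), AMHA_STATES)
    t <- t + chunk
  }
  d <- amha_derivatives(y, params, density)
  attr(y, "converged") <- max(abs(d)) < tol * max(N, 1)
  attr(y, "years") <- t
  y
}
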