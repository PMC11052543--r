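# Stochastic discrete-time AMHa dynamics on a static network.

#' Simulation configuration
#'
#' @param params an [amha_parameters()] (rates per reference period; the
#'   simulator converts them to per-year by linear scaling).
#' @param horizon_years simulated time span.
#' @param dt_years time step (default 1 year); every per-step probability
#'   must stay below 1 at the maximum observed neighbour counts, otherwise
#'   the simulation aborts asking for a smaller step.
#' @param replicates number of independent stochastic runs.
#' @param seed base RNG seed; replicate r uses `seed + r - 1`, which makes
#'   runs bit-reproducible and supports common random numbers across
#'   intervention arms.
#' @param scheme `"synchronous"` (all nodes update from the step-start
#'   neighbour counts; default) or `"asynchronous"` (random node order,
#'   counts updated as nodes change).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(params, horizon_years = 30, dt_years = 1,
                       replicates = 33, seed = 1,
                       scheme = c("synchronous", "asynchronous")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "amha_parameters"), horizon_years >= 0,
            dt_years > 0, replicates >= 1, seed == floor(seed))
  structure(list(params = params, horizon_years = horizon_years,
                 dt_years = dt_years, replicates = as.integer(replicates),
                 seed = as.integer(seed), scheme = scheme),
            class = "sim_config")
}

#' Per-step transition probabilities for one node
#'
#' Implements the discrete-time transition law: the probability of leaving
#' state X for Y over a step of length dt is
#' `(alpha_XY + sum_Z beta_XY^Z N_Z) * dt`, and the probability of staying
#' is one minus the sum of the two leave probabilities.
#'
#' @param state current state of the node ("A", "M" or "H").
#' @param counts named numeric `c(A=, M=, H=)` of neighbours per state.
#' @param params an [amha_parameters()].
#' @param dt_years step length.
#' @return named probability vector over A, M, H (summing to 1).
#' @export
step_probabilities <- function(state, counts, params, dt_years = 1) {
  stopifnot(state %in% AMHA_STATES, all(counts >= 0))
  counts <- counts[AMHA_STATES]
  ry <- rates_per_year(params)
  p <- setNames(numeric(3), AMHA_STATES)
  for (to in setdiff(AMHA_STATES, state))
    p[to] <- (ry$alpha[state, to] + sum(ry$beta[state, to, ] * counts)) *
      dt_years
  if (any(p < 0) || sum(p) > 1)
    stop("per-step leave probabilities exceed 1; use a smaller dt")
  p[state] <- 1 - sum(p)
  p
}

# per-year rate tables as plain arrays with zeros on the diagonal
.rate_tables <- function(params) {
  ry <- rates_per_year(params)
  a <- ry$alpha; a[is.na(a)] <- 0
  list(alpha = a, beta = ry$beta)
}

# one synchronous step for integer state vector s (1=A, 2=M, 3=H);
# counts is the n x 3 neighbour-count matrix at step start
.sync_step <- function(s, adj, rt, dt) {
  n <- length(s)
  ind <- matrix(0, n, 3); ind[cbind(seq_len(n), s)] <- 1
  counts <- as.matrix(adj %*% ind)
  P <- matrix(0, n, 3)
  for (x in 1:3) {
    idx <- which(s == x)
    if (!length(idx)) next
    for (y in setdiff(1:3, x))
      P[idx, y] <- (rt$alpha[x, y] +
                      counts[idx, , drop = FALSE] %*% rt$beta[x, y, ]) * dt
  }
  leave <- rowSums(P)
  if (any(P < 0) || any(leave > 1))
    stop("per-step leave probabilities exceed 1; use a smaller dt")
  P[cbind(seq_len(n), s)] <- 1 - leave
  u <- runif(n)
  cs1 <- P[, 1]; cs2 <- cs1 + P[, 2]
  ifelse(u <= cs1, 1L, ifelse(u <= cs2, 2L, 3L))
}

# asynchronous sweep: nodes updated one at a time in random order
.async_step <- function(s, nbrs, rt, dt) {
  for (i in sample.int(length(s))) {
    cnt <- tabulate(s[nbrs[[i]]], 3)
    x <- s[i]
    p <- numeric(3)
    for (y in setdiff(1:3, x))
      p[y] <- (rt$alpha[x, y] + sum(rt$beta[x, y, ] * cnt)) * dt
    if (any(p < 0) || sum(p) > 1)
      stop("per-step leave probabilities exceed 1; use a smaller dt")
    p[x] <- 1 - sum(p[-x])
    u <- runif(1)
    s[i] <- if (u <= p[1]) 1L else if (u <= p[1] + p[2]) 2L else 3L
  }
  s
}

#' Simulate AMHa dynamics on a static network
#'
#' Discrete-time stochastic simulation: at every step each node draws its
#' next state from [step_probabilities()] evaluated with neighbour counts
#' frozen at the step start (synchronous scheme). The node set is static
#' (no birth or mortality). Seeded runs are bit-reproducible.
#'
#' @param network an igraph network.
#' @param states named character vector of initial states covering every
#'   vertex (names are vertex names).
#' @param config a [sim_config()].
#' @return object of class `amha_sim`: `times` (years), `fractions`
#'   (array steps x 3 x replicates), `mean`, `ci_lo`, `ci_hi` (2.5/97.5
#'   replicate percentiles), `final_states` (matrix nodes x replicates),
#'   `config`.
#' @export
simulate_amha <- function(network, states, config) {
  stopifnot(inherits(config, "sim_config"))
  vn <- igraph::V(network)$name
  if (!all(vn %in% names(states)) || any(is.na(states[vn])))
    stop("every network node needs a known initial state")
  states <- states[vn]
  if (!all(states %in% AMHA_STATES)) stop("unknown state labels")
  s0 <- match(states, AMHA_STATES)
  n <- length(s0)
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  rt <- .rate_tables(config$params)
  dt <- config$dt_years
  n_steps <- if (config$horizon_years == 0) 0L
             else as.integer(round(config$horizon_years / dt))

  # guard: max total leave probability at the initial configuration
  ind <- matrix(0, n, 3); ind[cbind(seq_len(n), s0)] <- 1
  counts0 <- as.matrix(adj %*% ind)
  worst <- 0
  for (x in 1:3) {
    idx <- which(s0 == x)
    if (!length(idx)) next
    leave <- 0
    for (y in setdiff(1:3, x))
      leave <- leave + (rt$alpha[x, y] +
                          counts0[idx, , drop = FALSE] %*% rt$beta[x, y, ]) * dt
    worst <- max(worst, max(leave))
  }
  if (worst > 1)
    stop(sprintf("initial per-step leave probability up to %.3f > 1; use a smaller dt",
                 worst))

  nbrs <- if (config$scheme == "asynchronous")
    igraph::adjacent_vertices(network, igraph::V(network)) else NULL

  frac <- array(NA_real_, c(n_steps + 1, 3, config$replicates),
                dimnames = list(NULL, AMHA_STATES, NULL))
  finals <- matrix(NA_character_, n, config$replicates,
                   dimnames = list(vn, NULL))
  for (r in seq_len(config$replicates)) {
    set.seed(config$seed + r - 1L)
    s <- s0
    frac[1, , r] <- tabulate(s, 3) / n
    if (n_steps > 0) for (k in seq_len(n_steps)) {
      s <- if (config$scheme == "synchronous") .sync_step(s, adj, rt, dt)
           else .async_step(s, nbrs, rt, dt)
      frac[k + 1, , r] <- tabulate(s, 3) / n
    }
    finals[, r] <- AMHA_STATES[s]
  }
  res <- list(times = seq(0, by = dt, length.out = n_steps + 1),
              fractions = frac,
              mean = apply(frac, c(1, 2), mean),
              ci_lo = apply(frac, c(1, 2), quantile, 0.025, names = FALSE),
              ci_hi = apply(frac, c(1, 2), quantile, 0.975, names = FALSE),
              final_states = finals,
              config = config)
  class(res) <- "amha_sim"
  res
}

#' @export
print.amha_sim <- function(x, ...) {
  last <- nrow(x$mean)
  cat(sprintf("AMHa network simulation: %d nodes, %d replicates, %.0f years (dt = %g)\n",
              nrow(x$final_states), dim(x$fractions)[3],
              max(x$times), x$config$dt_years))
  cat(sprintf("Final mean fractions: A %.3f, M %.3f, H %.3f\n",
              x$mean[last, 1], x$mean[last, 2], x$mean[last, 3]))
  invisible(x)
}

#' Forecast from an observed wave on its network
#'
#' Takes the observed states at `wave` as the initial condition (nodes
#' with unknown state are dropped and counted), simulates forward on the
#' static network, aligns simulated steps to calendar years via the wave's
#' midpoint, and tabulates simulated against observed state fractions at
#' any later wave present in the panel.
#'
#' @param panel a [state_panel()].
#' @param network an igraph network.
#' @param params an [amha_parameters()].
#' @param wave wave index to start from.
#' @param horizon_years years to simulate.
#' @param ... passed to [sim_config()] (`dt_years`, `replicates`, `seed`...).
#' @return list of class `amha_forecast`: `sim` ([simulate_amha()] result),
#'   `calendar_years`, `comparison` (data.frame of observed vs simulated
#'   fractions per later wave), `n_dropped`.
#' @export
forecast_amha <- function(panel, network, params, wave, horizon_years = 30,
                          ...) {
  waves <- panel_waves(panel)
  stopifnot(wave %in% waves$wave)
  states <- .wave_states(panel, wave)
  vn <- igraph::V(network)$name
  known <- intersect(vn, names(states))
  n_dropped <- length(vn) - length(known)
  g <- igraph::induced_subgraph(network, known)
  config <- sim_config(params, horizon_years = horizon_years, ...)
  sim <- simulate_amha(g, states, config)
  year0 <- waves$midpoint_year[waves$wave == wave]
  cal <- year0 + sim$times

  later <- waves[waves$wave > wave, , drop = FALSE]
  comparison <- do.call(rbind, lapply(seq_len(nrow(later)), function(i) {
    w <- later$wave[i]; yr <- later$midpoint_year[i]
    obs <- .wave_states(panel, w)
    obs_frac <- as.numeric(table(factor(obs, AMHA_STATES)) / length(obs))
    ti <- which.min(abs(cal - yr))
    data.frame(wave = w, year = yr,
               obs_A = obs_frac[1], obs_M = obs_frac[2], obs_H = obs_frac[3],
               sim_A = sim$mean[ti, 1], sim_M = sim$mean[ti, 2],
               sim_H = sim$mean[ti, 3])
  }))
  structure(list(sim = sim, calendar_years = cal, comparison = comparison,
                 start_wave = wave, n_dropped = n_dropped),
            class = "amha_forecast")
}

#' @export
print.amha_forecast <- function(x, ...) {
  print(x$sim)
  if (!is.null(x$comparison) && nrow(x$comparison)) {
    cat("Observed vs simulated fractions at later waves:\n")
    print(round(x$comparison, 3))
  }
  invisible(x)
}
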