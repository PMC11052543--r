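# Validation statistics: stability/transition matrices, wave-to-wave state
# correlation, spatial correlation and clustering, chi-squared adjacency
# tests, cutoff sweeps, degree distribution, per-wave summaries.

# named state vector at one wave (NA dropped)
.wave_states <- function(panel, wave) {
  rec <- panel[panel$wave == wave & !is.na(panel$state), ]
  setNames(rec$state, rec$person_id)
}

# neighbour-state counts for every network vertex given a named state vector;
# unknown-state neighbours contribute nothing
.neighbor_counts <- function(states, network) {
  vnames <- igraph::V(network)$name
  vstate <- states[vnames]                      # NA where unknown / absent
  ind <- vapply(AMHA_STATES,
                function(s) as.numeric(!is.na(vstate) & vstate == s),
                numeric(length(vnames)))
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  counts <- as.matrix(adj %*% ind)
  dimnames(counts) <- list(vnames, AMHA_STATES)
  counts
}

#' Empirical wave-to-wave transition matrix
#'
#' Row-stochastic 3x3 matrix of the fraction of person-waves in state X
#' observed in state Y at the next wave, pooled over all wave pairs.
#'
#' @param transitions an [extract_transitions()] result (or any data.frame
#'   with `from_state`, `to_state`).
#' @return matrix of class `amha_transition_matrix` with attribute `n_obs`
#'   (origin-state counts).
#' @export
transition_matrix <- function(transitions) {
  if (nrow(transitions) == 0) stop("no transitions")
  tab <- table(factor(transitions$from_state, AMHA_STATES),
               factor(transitions$to_state, AMHA_STATES))
  n_obs <- rowSums(tab)
  P <- sweep(unclass(tab), 1, pmax(n_obs, 1), "/")
  dimnames(P) <- list(AMHA_STATES, AMHA_STATES)
  structure(P, n_obs = n_obs, class = c("amha_transition_matrix", "matrix"))
}

#' @export
print.amha_transition_matrix <- function(x, digits = 3, ...) {
  cat("Transition matrix (rows: from, columns: to)\n")
  print(round(unclass(x), digits))
  cat("n_obs:", paste(AMHA_STATES, attr(x, "n_obs"), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Annualize a stay probability
#'
#' Converts a per-interval stay probability to a yearly one. The default
#' `"geometric"` method takes the interval-th root of the scalar stay
#' probability, assuming no unobserved switching within the interval. The
#' `"matrix_root"` method takes the diagonal of the interval-th root of a
#' full transition matrix (computed by eigendecomposition), which accounts
#' for round trips through other states; it is unavailable (all `NA`) when
#' no real stochastic root exists.
#'
#' @param x a stay probability in (0, 1] (vectorized), or for
#'   `method = "matrix_root"` an [transition_matrix()] result.
#' @param interval_years positive interval length.
#' @param method `"geometric"` or `"matrix_root"`.
#' @return numeric vector of yearly stay probabilities (the matrix-root
#'   method returns the three diagonal entries).
#' @export
annualize_stability <- function(x, interval_years,
                                method = c("geometric", "matrix_root")) {
  method <- match.arg(method)
  stopifnot(interval_years > 0)
  if (method == "geometric") {
    stopifnot(is.numeric(x), all(x > 0 & x <= 1, na.rm = TRUE))
    return(x^(1 / interval_years))
  }
  P <- unclass(x)
  stopifnot(is.matrix(P), nrow(P) == 3, ncol(P) == 3)
  eg <- eigen(P)
  if (any(Re(eg$values) <= 0 & abs(Im(eg$values)) < 1e-12)) {
    warning("no real stochastic matrix root; annualized matrix unavailable")
    return(setNames(rep(NA_real_, 3), AMHA_STATES))
  }
  root <- eg$vectors %*% diag(as.complex(eg$values)^(1 / interval_years)) %*%
    solve(eg$vectors)
  if (max(abs(Im(root))) > 1e-8 || any(Re(root) < -1e-8)) {
    warning("no real stochastic matrix root; annualized matrix unavailable")
    return(setNames(rep(NA_real_, 3), AMHA_STATES))
  }
  setNames(pmin(pmax(Re(diag(root)), 0), 1), AMHA_STATES)
}

#' Wave-to-wave state correlation
#'
#' Pearson correlation between each person's drinking state at consecutive
#' waves, on the ordinal scale A = 0, M = 1, H = 2, over persons observed
#' at both waves. High values indicate that states are stable on the
#' multi-year timescale of the examination interval.
#'
#' @param panel a [state_panel()].
#' @return data.frame with `wave`, `wave_next`, `n`, `r`, plus attribute
#'   `mean_r` (unweighted mean over wave pairs).
#' @export
state_correlation_by_wave <- function(panel) {
  waves <- panel_waves(panel)
  if (nrow(waves) < 2) stop("need at least two waves")
  code <- setNames(0:2, AMHA_STATES)
  out <- data.frame(wave = integer(), wave_next = integer(),
                    n = integer(), r = numeric())
  for (wi in seq_len(nrow(waves) - 1)) {
    s1 <- .wave_states(panel, waves$wave[wi])
    s2 <- .wave_states(panel, waves$wave[wi + 1])
    common <- intersect(names(s1), names(s2))
    r <- if (length(common) >= 3)
      cor(code[s1[common]], code[s2[common]]) else NA_real_
    out <- rbind(out, data.frame(wave = waves$wave[wi],
                                 wave_next = waves$wave[wi + 1],
                                 n = length(common), r = r))
  }
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  out
}

# core computation for a single wave's spatial correlation
.spatial_one_wave <- function(states, network) {
  known <- names(states)
  g <- igraph::induced_subgraph(network,
                                intersect(igraph::V(network)$name, known))
  vn <- igraph::V(g)$name
  n <- length(vn)
  st <- states[vn]
  nX <- vapply(AMHA_STATES, function(s) sum(st == s), numeric(1))
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  Osym <- matrix(0, 3, 3, dimnames = list(AMHA_STATES, AMHA_STATES))
  if (m > 0) {
    a <- st[el[, 1]]; b <- st[el[, 2]]
    lo <- pmin(a, b); hi <- pmax(a, b)   # canonical endpoint order per edge
    tab <- unclass(table(factor(lo, AMHA_STATES), factor(hi, AMHA_STATES)))
    Osym <- tab + t(tab)
    diag(Osym) <- diag(tab)
    dimnames(Osym) <- list(AMHA_STATES, AMHA_STATES)
  }
  E <- matrix(NA_real_, 3, 3, dimnames = list(AMHA_STATES, AMHA_STATES))
  if (n >= 2) {
    for (X in AMHA_STATES) for (Y in AMHA_STATES) {
      E[X, Y] <- if (X == Y) m * nX[X] * (nX[X] - 1) / (n * (n - 1))
                 else m * 2 * nX[X] * nX[Y] / (n * (n - 1))
    }
  }
  C <- ifelse(E > 0, Osym / E, NA_real_)
  list(observed = Osym, expected = E, C = C, m = m, n = n, n_states = nX)
}

#' Spatial correlation and clustering of states over network edges
#'
#' `C[X, Y]` is the observed number of edges joining a state-X and a
#' state-Y node divided by its expectation under random permutation of the
#' observed state labels over the same nodes with the graph held fixed
#' (computed analytically: for X != Y, `E = m * 2 n_X n_Y / (n (n-1))`;
#' for X = Y, `E = m * n_X (n_X - 1) / (n (n-1))`, with `m` edges among
#' `n` state-known nodes). Diagonal cells are called clustering. Cells for
#' states absent at a wave are `NA` (undefined, not zero). With several
#' waves the matrices are the unweighted mean of per-wave matrices.
#'
#' @param panel a [state_panel()].
#' @param network an igraph network.
#' @param wave optional single wave index; default: average over all waves.
#' @return list of class `spatial_correlation` with matrices `C`,
#'   `observed`, `expected`, and `per_wave` (when averaged).
#' @export
spatial_correlation <- function(panel, network, wave = NULL) {
  waves <- if (is.null(wave)) panel_waves(panel)$wave else wave
  per <- lapply(waves, function(w) .spatial_one_wave(.wave_states(panel, w), network))
  names(per) <- waves
  avg <- function(field) {
    arr <- simplify2array(lapply(per, `[[`, field))
    apply(arr, c(1, 2), mean, na.rm = FALSE)
  }
  res <- list(C = avg("C"), observed = avg("observed"),
              expected = avg("expected"),
              per_wave = if (length(per) > 1) per else NULL,
              waves = waves)
  class(res) <- "spatial_correlation"
  res
}

#' @export
print.spatial_correlation <- function(x, digits = 2, ...) {
  cat("Spatial correlation / clustering C[X,Y]",
      if (length(x$waves) > 1) sprintf("(mean over %d waves)", length(x$waves)),
      "\n")
  print(round(x$C, digits))
  invisible(x)
}

#' Chi-squared test of ego-state vs neighbour-state independence
#'
#' Builds the 2x3 contingency table of (ego is in `ego_state`: yes/no) by
#' (neighbour state A/M/H), counting ordered ego-neighbour pairs with both
#' states known at the wave, and applies Pearson's chi-squared test without
#' continuity correction (df = 2).
#'
#' @param panel a [state_panel()].
#' @param network an igraph network.
#' @param wave wave index.
#' @param ego_state focal state, one of "A", "M", "H".
#' @return list with `statistic`, `df`, `p_value`, `N` (ordered pairs),
#'   `table`, and `low_expected` (TRUE if any expected cell < 5).
#' @export
chisq_state_adjacency <- function(panel, network, wave, ego_state) {
  stopifnot(ego_state %in% AMHA_STATES)
  states <- .wave_states(panel, wave)
  counts <- .neighbor_counts(states, network)
  egos <- intersect(rownames(counts), names(states))
  counts <- counts[egos, , drop = FALSE]
  in_state <- states[egos] == ego_state
  tab <- rbind(colSums(counts[in_state, , drop = FALSE]),
               colSums(counts[!in_state, , drop = FALSE]))
  dimnames(tab) <- list(c(ego_state, paste0("not_", ego_state)), AMHA_STATES)
  if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2)
    stop("degenerate contingency table: a row or all but one column is empty")
  keep_cols <- colSums(tab) > 0
  ct <- suppressWarnings(stats::chisq.test(tab[, keep_cols, drop = FALSE],
                                           correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, N = sum(tab), table = tab,
       low_expected = any(ct$expected < 5))
}

# per-period stay probabilities under an arbitrary cutoff, from raw panel
.stay_probs <- function(panel, policy) {
  st <- classify_state(panel$drinks_per_week, panel$sex, policy)
  waves <- panel_waves(panel)
  stay <- matrix(0, 2, 3, dimnames = list(c("stay", "total"), AMHA_STATES))
  mean_dt <- mean(waves$interval_years, na.rm = TRUE)
  key <- paste(panel$person_id, panel$wave)
  idx <- setNames(seq_along(key), key)
  for (wi in seq_len(nrow(waves) - 1)) {
    k1 <- paste(panel$person_id, waves$wave[wi])
    k2 <- paste(panel$person_id, waves$wave[wi + 1])
    i1 <- idx[k1]; i2 <- idx[k2]
    ok <- !is.na(i1) & !is.na(i2)
    s1 <- st[i1[ok]]; s2 <- st[i2[ok]]
    ok2 <- !is.na(s1) & !is.na(s2)
    s1 <- s1[ok2]; s2 <- s2[ok2]
    for (s in AMHA_STATES) {
      stay["total", s] <- stay["total", s] + sum(s1 == s)
      stay["stay", s] <- stay["stay", s] + sum(s1 == s & s2 == s)
    }
  }
  p <- stay["stay", ] / pmax(stay["total", ], 1)
  p[stay["total", ] == 0] <- NA_real_
  list(per_period = p, mean_interval = mean_dt, n = stay["total", ])
}

#' Stability of drinking states across moderate-to-heavy cutoffs
#'
#' For each female threshold in the grid (male = twice the female value),
#' all person-waves are re-classified and the annualized stay probability
#' of each state is recomputed. `stay_MH`, the combined drinking-state
#' stability, is the unweighted mean of the moderate and heavy category
#' stabilities (each state weighted equally; a pooled or superset reading
#' would be monotone in the cutoff by construction and carry no
#' information). The combined stability peaking near the conventional
#' 7/14 drinks-per-week cutoff supports that cutoff behaviourally.
#'
#' @param panel a [state_panel()].
#' @param cutoff_grid strictly increasing female thresholds (drinks/week).
#' @return data.frame of class `stability_curve`: `cutoff_female`,
#'   `cutoff_male`, annualized `stay_A`, `stay_M`, `stay_H`, `stay_MH`.
#' @export
stability_cutoff_sweep <- function(panel, cutoff_grid = 1:21) {
  stopifnot(all(cutoff_grid > 0), !is.unsorted(cutoff_grid, strictly = TRUE))
  rows <- lapply(cutoff_grid, function(f) {
    sp <- .stay_probs(panel, cutoff_policy(f))
    ann <- annualize_stability(pmax(sp$per_period, 1e-12), sp$mean_interval)
    ann[is.na(sp$per_period)] <- NA_real_
    data.frame(cutoff_female = f, cutoff_male = 2 * f,
               stay_A = ann[["A"]], stay_M = ann[["M"]],
               stay_H = ann[["H"]],
               stay_MH = mean(c(ann[["M"]], ann[["H"]]), na.rm = TRUE))
  })
  structure(do.call(rbind, rows), class = c("stability_curve", "data.frame"))
}

#' @export
plot.stability_curve <- function(x, ...) {
  graphics::matplot(x$cutoff_female,
                    cbind(x$stay_A, x$stay_M, x$stay_H, x$stay_MH),
                    type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "grey40", "firebrick", "black"),
                    xlab = "moderate/heavy cutoff, drinks per week (women)",
                    ylab = "annualized stay probability", ...)
  graphics::legend("bottomright", c("A", "M", "H", "M+H"), lty = 1, lwd = 2,
                   col = c("steelblue", "grey40", "firebrick", "black"))
  invisible(x)
}

#' Degree distribution of the network
#'
#' @param network an igraph network.
#' @param nodes optional character vector restricting to a node subset
#'   (e.g. state-known persons); degrees are recomputed on the induced
#'   subgraph.
#' @return data.frame with `degree`, `count`; attribute `mean_degree`.
#' @export
degree_distribution_amha <- function(network, nodes = NULL) {
  g <- if (is.null(nodes)) network
       else igraph::induced_subgraph(network,
                                     intersect(igraph::V(network)$name, nodes))
  deg <- igraph::degree(g)
  tab <- table(deg)
  out <- data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  attr(out, "mean_degree") <- if (length(deg)) mean(deg) else NA_real_
  out
}

#' Per-wave descriptive summary
#'
#' One row per wave: number of state-known egos, mean age, mean drinks per
#' day (drinks per week / 7), mean number of state-known contacts, and the
#' mean number (and percentage) of contacts abstaining and drinking
#' heavily.
#'
#' @param panel a [state_panel()].
#' @param network an igraph network.
#' @return data.frame, one row per wave plus a `Mean` row.
#' @export
wave_summary <- function(panel, network) {
  waves <- panel_waves(panel)
  rows <- lapply(seq_len(nrow(waves)), function(wi) {
    w <- waves$wave[wi]
    rec <- panel[panel$wave == w & !is.na(panel$state), ]
    states <- setNames(rec$state, rec$person_id)
    counts <- .neighbor_counts(states, network)
    egos <- intersect(rec$person_id, rownames(counts))
    cts <- matrix(0, nrow(rec), 3, dimnames = list(rec$person_id, AMHA_STATES))
    cts[egos, ] <- counts[egos, , drop = FALSE]
    tot <- rowSums(cts)
    data.frame(wave = w, midpoint_year = waves$midpoint_year[wi],
               egos = nrow(rec),
               mean_age = mean(rec$age, na.rm = TRUE),
               drinks_per_day = mean(rec$drinks_per_week, na.rm = TRUE) / 7,
               contacts = mean(tot),
               contacts_abstain = mean(cts[, "A"]),
               pct_contacts_abstain = 100 * sum(cts[, "A"]) / max(sum(tot), 1),
               contacts_heavy = mean(cts[, "H"]),
               pct_contacts_heavy = 100 * sum(cts[, "H"]) / max(sum(tot), 1))
  })
  out <- do.call(rbind, rows)
  mean_row <- out[1, ]
  mean_row$wave <- NA; mean_row$midpoint_year <- NA
  for (col in names(out)[-(1:2)]) mean_row[[col]] <- mean(out[[col]])
  rbind(out, Mean = mean_row)
}
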