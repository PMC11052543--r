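# AMHa parameter container: spontaneous rates alpha[X,Y] and social rates
# beta[X,Y,Z] (per neighbour in state Z), all per reference period.

#' AMHa model parameters
#'
#' Container for the calibrated (or true) transition rates. `alpha[X, Y]` is
#' the spontaneous probability of an X-to-Y transition per reference period;
#' `beta[X, Y, Z]` is the additional probability per network neighbour in
#' state Z. All rates must be non-negative; off-model entries (the
#' diagonal) are `NA` in `alpha` and 0 in `beta`.
#'
#' @param alpha 3x3 numeric matrix (dimnames A/M/H), diagonal ignored.
#' @param beta 3x3x3 numeric array `[from, to, influencer]` (default all 0).
#' @param se,p optional lists with elements `alpha` (3x3) and `beta`
#'   (3x3x3): standard errors and p-values from calibration.
#' @param significant optional logical 3x3x3 array flagging retained betas.
#' @param reference_period_years period the rates are expressed in
#'   (default 4 years).
#' @return object of class `amha_parameters`.
#' @export
amha_parameters <- function(alpha, beta = NULL, se = NULL, p = NULL,
                            significant = NULL, reference_period_years = 4) {
  s <- AMHA_STATES
  alpha <- as.matrix(alpha)
  dimnames(alpha) <- list(s, s)
  diag(alpha) <- NA_real_
  if (is.null(beta)) beta <- array(0, c(3, 3, 3))
  dimnames(beta) <- list(s, s, s)
  for (z in s) diag(beta[, , z]) <- 0
  if (any(alpha < 0, na.rm = TRUE) || any(beta < 0))
    stop("rates must be non-negative")
  stopifnot(reference_period_years > 0)
  structure(list(alpha = alpha, beta = beta, se = se, p = p,
                 significant = significant,
                 reference_period_years = reference_period_years),
            class = "amha_parameters")
}

#' @export
print.amha_parameters <- function(x, ...) {
  s <- AMHA_STATES
  cat(sprintf("AMHa rates per %g-year period\n", x$reference_period_years))
  for (from in s) for (to in s) {
    if (from == to) next
    line <- sprintf("  %s -> %s : alpha = %.4f", from, to, x$alpha[from, to])
    bz <- x$beta[from, to, ]
    for (z in s[bz > 0])
      line <- paste0(line, sprintf(", beta^%s = %.4f", z, bz[z]))
    cat(line, "\n")
  }
  invisible(x)
}

#' Convert rates to per-year scale
#'
#' Linear rescaling by the reference period (rates are probabilities per
#' period and the model is linear in time over small intervals).
#'
#' @param params an [amha_parameters()] object.
#' @return list with `alpha` and `beta` per year.
#' @export
rates_per_year <- function(params) {
  list(alpha = params$alpha / params$reference_period_years,
       beta = params$beta / params$reference_period_years)
}

#' Check that per-step transition probabilities stay below one
#'
#' Computes, for each possible origin state, the total leave probability at
#' the given neighbour counts and time step, and errors if any exceeds 1.
#'
#' @param params an [amha_parameters()].
#' @param max_counts named numeric vector, maximum neighbour counts per
#'   state (e.g. the max degree in each state).
#' @param dt_years time step.
#' @return invisibly, the per-origin-state maximum total leave probability.
#' @export
check_step_probabilities <- function(params, max_counts, dt_years = 1) {
  s <- AMHA_STATES
  max_counts <- max_counts[s]
  ry <- rates_per_year(params)
  tot <- setNames(numeric(3), s)
  for (from in s) {
    leave <- 0
    for (to in setdiff(s, from))
      leave <- leave + (ry$alpha[from, to] +
                          sum(ry$beta[from, to, ] * max_counts)) * dt_years
    tot[from] <- leave
  }
  if (any(tot > 1))
    stop("total per-step leave probability exceeds 1 (max ",
         sprintf("%.3f", max(tot)), "); use a smaller dt")
  invisible(tot)
}

#' Serialize / deserialize AMHa parameters as JSON
#'
#' The JSON maps each transition `"X->Y"` to its alpha and a
#' `beta_by_influencer` object, with standard errors, p-values and
#' significance flags when present.
#'
#' @param params an [amha_parameters()].
#' @param path JSON file path.
#' @return `read_params` returns an [amha_parameters()]; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  s <- AMHA_STATES
  trans <- list()
  for (from in s) for (to in s) {
    if (from == to) next
    key <- paste0(from, "->", to)
    entry <- list(alpha = params$alpha[from, to],
                  beta_by_influencer = as.list(params$beta[from, to, ]))
    if (!is.null(params$se)) {
      entry$se_alpha <- params$se$alpha[from, to]
      entry$se_beta <- as.list(params$se$beta[from, to, ])
    }
    if (!is.null(params$p)) {
      entry$p_alpha <- params$p$alpha[from, to]
      entry$p_beta <- as.list(params$p$beta[from, to, ])
    }
    if (!is.null(params$significant))
      entry$significant <- as.list(params$significant[from, to, ])
    trans[[key]] <- entry
  }
  jsonlite::write_json(
    list(reference_period_years = params$reference_period_years,
         transitions = trans),
    path, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  s <- AMHA_STATES
  alpha <- matrix(NA_real_, 3, 3, dimnames = list(s, s))
  beta <- array(0, c(3, 3, 3), dimnames = list(s, s, s))
  has_se <- has_p <- has_sig <- FALSE
  na_beta <- array(NA_real_, c(3, 3, 3), dimnames = list(s, s, s))
  se <- list(alpha = alpha, beta = na_beta)
  p <- list(alpha = alpha, beta = na_beta)
  sig <- array(FALSE, c(3, 3, 3), dimnames = list(s, s, s))
  for (key in names(obj$transitions)) {
    e <- obj$transitions[[key]]
    pair <- strsplit(key, "->", fixed = TRUE)[[1]]
    from <- pair[1]; to <- pair[2]
    alpha[from, to] <- as.numeric(e$alpha)
    for (z in names(e$beta_by_influencer))
      beta[from, to, z] <- as.numeric(e$beta_by_influencer[[z]])
    if (!is.null(e$se_alpha)) {
      has_se <- TRUE
      se$alpha[from, to] <- as.numeric(e$se_alpha)
      for (z in names(e$se_beta))
        se$beta[from, to, z] <- nanull(e$se_beta[[z]])
    }
    if (!is.null(e$p_alpha)) {
      has_p <- TRUE
      p$alpha[from, to] <- as.numeric(e$p_alpha)
      for (z in names(e$p_beta))
        p$beta[from, to, z] <- nanull(e$p_beta[[z]])
    }
    if (!is.null(e$significant)) {
      has_sig <- TRUE
      for (z in names(e$significant))
        sig[from, to, z] <- isTRUE(e$significant[[z]])
    }
  }
  amha_parameters(alpha, beta,
                  se = if (has_se) se else NULL,
                  p = if (has_p) p else NULL,
                  significant = if (has_sig) sig else NULL,
                  reference_period_years = as.numeric(obj$reference_period_years))
}

nanull <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Text rate diagram
#'
#' Renders the calibrated model as a compact text table: one line per
#' transition with its spontaneous rate and any retained social rates
#' (marked with the influencer state).
#'
#' @param params an [amha_parameters()].
#' @return character vector of lines (also printed invisibly-friendly).
#' @export
rate_diagram <- function(params) {
  s <- AMHA_STATES
  lines <- sprintf("AMHa calibrated rates (per %g years)",
                   params$reference_period_years)
  for (from in s) for (to in s) {
    if (from == to) next
    social <- ""
    bz <- params$beta[from, to, ]
    for (z in s[bz > 0])
      social <- paste0(social, sprintf("  + %.4f per %s-neighbour", bz[z], z))
    lines <- c(lines, sprintf("  %s -> %s  alpha %.4f%s", from, to,
                              params$alpha[from, to], social))
  }
  lines
}

#' Default ground-truth parameters for synthetic scenarios
#'
#' A parameter set of the magnitudes seen in longitudinal drinking-panel
#' calibrations (spontaneous rates 0.01-0.25 per 4-year period, social
#' rates 0.02-0.04 per neighbour per period). Each transition carries at
#' most one social term, the one whose influencer is the destination state,
#' so single-regressor calibration is unbiased on data generated from it:
#' moderate drinkers pull abstainers into drinking (beta_AM^M), heavy
#' neighbours pull moderates to heavy (beta_MH^H), and abstaining
#' neighbours pull both moderates and heavy drinkers toward abstinence
#' (beta_MA^A, beta_HA^A). Direct A-to-H superinfection is rare and purely
#' spontaneous.
#'
#' @param reference_period_years rate period, default 4.
#' @return an [amha_parameters()] object.
#' @export
default_true_params <- function(reference_period_years = 4) {
  s <- AMHA_STATES
  alpha <- matrix(NA_real_, 3, 3, dimnames = list(s, s))
  alpha["A", "M"] <- 0.18; alpha["A", "H"] <- 0.01
  alpha["M", "A"] <- 0.10; alpha["M", "H"] <- 0.08
  alpha["H", "M"] <- 0.25; alpha["H", "A"] <- 0.07
  beta <- array(0, c(3, 3, 3), dimnames = list(s, s, s))
  beta["A", "M", "M"] <- 0.020
  beta["M", "H", "H"] <- 0.040
  beta["M", "A", "A"] <- 0.025
  beta["H", "A", "A"] <- 0.035
  amha_parameters(alpha, beta, reference_period_years = reference_period_years)
}
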