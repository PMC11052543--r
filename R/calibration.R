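# Calibration of spontaneous (alpha) and social (beta) transition rates by
# weighted least squares on aggregated transition fractions.

#' Aggregate transitions by neighbour count
#'
#' Among records starting in `from_state`, groups by the number of
#' neighbours in `influencer` state and computes the fraction transitioning
#' to `to_state`, together with the at-risk count used as regression
#' weight.
#'
#' @param transitions an [extract_transitions()] result.
#' @param from_state,to_state origin and destination states (distinct).
#' @param influencer neighbour state whose count is the regressor.
#' @return data.frame with `k` (neighbour count), `fraction`, `n`
#'   (at-risk), `n_transitions`.
#' @export
aggregate_by_neighbor_count <- function(transitions, from_state, to_state,
                                        influencer) {
  stopifnot(from_state %in% AMHA_STATES, to_state %in% AMHA_STATES,
            influencer %in% AMHA_STATES, from_state != to_state)
  at_risk <- transitions[transitions$from_state == from_state, , drop = FALSE]
  if (nrow(at_risk) == 0)
    return(data.frame(k = numeric(), fraction = numeric(), n = numeric(),
                      n_transitions = numeric()))
  k <- at_risk[[paste0("n_", influencer)]]
  hit <- as.numeric(at_risk$to_state == to_state)
  n <- tapply(hit, k, length)
  y <- tapply(hit, k, sum)
  data.frame(k = as.numeric(names(n)), fraction = as.numeric(y / n),
             n = as.numeric(n), n_transitions = as.numeric(y),
             row.names = NULL)
}

#' Weighted least squares fit of transition fraction on neighbour count
#'
#' Regresses the per-`k` transition fraction on `k` with weights equal to
#' the at-risk counts. The point estimates are identical to an ordinary
#' least squares regression of the individual binary transition indicators
#' on `k`, and the standard errors and two-sided t-based p-values are
#' computed on that individual-level equivalence (residual degrees of
#' freedom `n_total - 2`, residual variance pooling the within-cell
#' binomial part with the lack-of-fit part). Aggregated-level residual
#' variance would rest on a handful of `k` cells and make the t statistics
#' heavy-tailed. The intercept estimates the spontaneous rate alpha and
#' the slope the social rate beta (per neighbour), both on the scale of
#' the observation interval. With a single distinct `k` only the intercept
#' is returned (slope `NA`). With all weights equal the point estimates
#' reduce exactly to ordinary least squares on the fractions.
#'
#' @param points output of [aggregate_by_neighbor_count()].
#' @return list of class `amha_fit`: `intercept`, `slope`, their standard
#'   errors and two-sided p-values, `n_points`, `n_total`, `points`.
#' @export
fit_wls <- function(points) {
  if (nrow(points) == 0) stop("no aggregated points to fit")
  out <- list(points = points, n_points = nrow(points),
              n_total = sum(points$n))
  N <- sum(points$n)
  f <- points$fraction
  if (length(unique(points$k)) < 2) {
    p_hat <- weighted.mean(f, points$n)
    out$intercept <- p_hat
    df <- N - 1
    sigma2 <- sum(points$n * (f * (1 - f) + (f - p_hat)^2)) / max(df, 1)
    out$se_intercept <- sqrt(sigma2 / N)
    out$p_intercept <- if (df > 0 && out$se_intercept > 0)
      2 * stats::pt(-abs(p_hat / out$se_intercept), df) else NA_real_
    out$slope <- NA_real_; out$se_slope <- NA_real_; out$p_slope <- NA_real_
  } else {
    fit <- lm(fraction ~ k, data = points, weights = n)
    cf <- coef(fit)
    out$intercept <- unname(cf[1]); out$slope <- unname(cf[2])
    yhat <- unname(fitted(fit))
    df <- N - 2
    # individual-level RSS: within-cell binomial scatter + lack of fit
    sigma2 <- sum(points$n * (f * (1 - f) + (f - yhat)^2)) / max(df, 1)
    XtWX <- rbind(c(N, sum(points$n * points$k)),
                  c(sum(points$n * points$k), sum(points$n * points$k^2)))
    covm <- sigma2 * solve(XtWX)
    ses <- sqrt(diag(covm))
    out$se_intercept <- ses[1]; out$se_slope <- ses[2]
    tv <- cf / ses
    pv <- if (df > 0) 2 * stats::pt(-abs(tv), df) else rep(NA_real_, 2)
    out$p_intercept <- unname(pv[1]); out$p_slope <- unname(pv[2])
  }
  class(out) <- "amha_fit"
  out
}

#' @export
print.amha_fit <- function(x, ...) {
  cat(sprintf("WLS fit%s: intercept %.4f (se %.4f, p %.3g)",
              if (!is.null(x$transition))
                paste0(" ", x$transition,
                       if (!is.null(x$influencer)) paste0(" | N_", x$influencer))
              else "",
              x$intercept, x$se_intercept, x$p_intercept))
  if (!is.na(x$slope))
    cat(sprintf(", slope %.4f (se %.4f, p %.3g)", x$slope, x$se_slope, x$p_slope))
  cat(sprintf(" [%d points, %d at-risk]\n", x$n_points, x$n_total))
  invisible(x)
}

#' Compare the linear fit with logistic regression
#'
#' Fits a logistic regression of the binary transition indicator on the
#' neighbour count at the individual-record level and compares its
#' predicted per-`k` probabilities with the weighted linear fit. At the low
#' per-interval rates and low degrees typical of these panels the two
#' agree closely; a large divergence flags that the linear approximation
#' is outside its range.
#'
#' @param transitions an [extract_transitions()] result.
#' @param from_state,to_state,influencer as in [aggregate_by_neighbor_count()].
#' @param flag_threshold divergence above which `nonlinear` is set
#'   (default 0.02).
#' @return list with per-`k` predictions from both models, the maximum
#'   absolute divergence, and a `nonlinear` flag.
#' @export
fit_logistic_check <- function(transitions, from_state, to_state, influencer,
                               flag_threshold = 0.02) {
  points <- aggregate_by_neighbor_count(transitions, from_state, to_state,
                                        influencer)
  if (nrow(points) == 0) stop("no at-risk records")
  wls <- fit_wls(points)
  lin_pred <- if (is.na(wls$slope)) rep(wls$intercept, nrow(points))
              else wls$intercept + wls$slope * points$k
  lin_pred <- pmin(pmax(lin_pred, 0), 1)
  if (length(unique(points$k)) < 2) {
    logit_pred <- rep(sum(points$n_transitions) / sum(points$n), nrow(points))
  } else {
    gfit <- glm(cbind(n_transitions, n - n_transitions) ~ k,
                family = binomial(), data = points)
    logit_pred <- as.numeric(predict(gfit, type = "response"))
  }
  divergence <- max(abs(lin_pred - logit_pred))
  list(points = points, linear = lin_pred, logistic = logit_pred,
       max_divergence = divergence,
       nonlinear = divergence > flag_threshold)
}

# the six ordered transitions
.transition_pairs <- function() {
  pairs <- expand.grid(from = AMHA_STATES, to = AMHA_STATES,
                       stringsAsFactors = FALSE)
  pairs[pairs$from != pairs$to, ]
}

#' Calibrate AMHa parameters from transition records
#'
#' For each of the six ordered transitions X -> Y the primary regression
#' uses the count of neighbours in the destination state Y; configured
#' cross terms add regressions on other influencer states (by default the
#' pull of heavy neighbours on abstainers starting to drink, and of
#' abstaining neighbours on heavy drinkers cutting down to moderate).
#' The spontaneous rate alpha is the intercept of the primary fit
#' (clamped at zero if negative); a social rate beta is retained only when
#' its slope is positive with p below `significance_level`, otherwise it
#' is set to zero. Estimates are rescaled linearly from the observation
#' interval to `reference_period_years`.
#'
#' @param transitions an [extract_transitions()] result.
#' @param significance_level retention threshold for social slopes
#'   (default 0.05; no multiple-testing correction is applied).
#' @param cross_terms list of `c(from, to, influencer)` triples tested in
#'   addition to the primary (influencer = destination) terms.
#' @param reference_period_years scale of the reported rates; default 4,
#'   or the (constant) observation interval when all pairs share one.
#' @return an [amha_parameters()] object; all [fit_wls()] objects are
#'   attached as attribute `fits` (named `"X->Y|Z"`).
#' @export
calibrate <- function(transitions, significance_level = 0.05,
                      cross_terms = list(c("A", "M", "H"), c("H", "M", "A")),
                      reference_period_years = 4) {
  s <- AMHA_STATES
  if (nrow(transitions) == 0) stop("no transitions to calibrate on")
  ivals <- unique(transitions$interval_years)
  mean_interval <- weighted.mean(transitions$interval_years)
  if (length(ivals) > 1)
    warning("pooling wave pairs with different intervals (",
            paste(signif(ivals, 3), collapse = ", "),
            "); rates rescaled from the mean interval")
  scale <- reference_period_years / mean_interval

  pairs <- .transition_pairs()
  missing_origin <- setdiff(s, unique(transitions$from_state))
  if (length(missing_origin))
    stop("no at-risk observations for origin state(s): ",
         paste(missing_origin, collapse = ", "))

  alpha <- matrix(NA_real_, 3, 3, dimnames = list(s, s))
  beta <- array(0, c(3, 3, 3), dimnames = list(s, s, s))
  se <- list(alpha = alpha, beta = array(NA_real_, c(3, 3, 3),
                                         dimnames = list(s, s, s)))
  p <- list(alpha = alpha, beta = array(NA_real_, c(3, 3, 3),
                                        dimnames = list(s, s, s)))
  sig <- array(FALSE, c(3, 3, 3), dimnames = list(s, s, s))
  fits <- list()

  terms <- lapply(seq_len(nrow(pairs)), function(i)
    c(pairs$from[i], pairs$to[i], pairs$to[i]))      # primary: Z = Y
  for (ct in cross_terms)
    if (!any(vapply(terms, function(t) all(t == ct), logical(1))))
      terms <- c(terms, list(ct))

  for (t in terms) {
    from <- t[1]; to <- t[2]; z <- t[3]
    points <- aggregate_by_neighbor_count(transitions, from, to, z)
    fit <- fit_wls(points)
    fit$transition <- paste0(from, "->", to); fit$influencer <- z
    fits[[paste0(from, "->", to, "|", z)]] <- fit
    if (z == to) {            # primary fit carries the spontaneous rate
      alpha[from, to] <- max(fit$intercept, 0) * scale
      se$alpha[from, to] <- fit$se_intercept * scale
      p$alpha[from, to] <- fit$p_intercept
    }
    if (!is.na(fit$slope)) {
      se$beta[from, to, z] <- fit$se_slope * scale
      p$beta[from, to, z] <- fit$p_slope
      keep <- fit$slope > 0 && fit$p_slope <= significance_level
      sig[from, to, z] <- keep
      if (keep) beta[from, to, z] <- fit$slope * scale
    }
  }

  params <- amha_parameters(alpha, beta, se = se, p = p, significant = sig,
                            reference_period_years = reference_period_years)
  # total one-period leave probability at every observed neighbour context
  ry <- rates_per_year(params)
  leave <- numeric(nrow(transitions))
  cts <- as.matrix(transitions[, c("n_A", "n_M", "n_H")])
  for (from in s) {
    idx <- transitions$from_state == from
    if (!any(idx)) next
    for (to in setdiff(s, from))
      leave[idx] <- leave[idx] +
        (ry$alpha[from, to] + cts[idx, , drop = FALSE] %*%
           ry$beta[from, to, ]) * transitions$interval_years[idx]
  }
  if (max(leave) > 1)
    warning("calibrated rates imply a per-interval transition probability of ",
            sprintf("%.3f", max(leave)), " > 1 at an observed context")
  attr(params, "fits") <- fits
  attr(params, "significance_level") <- significance_level
  params
}

#' Per-wave calibration and trend over time
#'
#' Fits the primary regression of each transition separately for every
#' wave pair, then tests for a linear trend of the per-wave estimates over
#' the wave midpoint (weighted by inverse squared standard error). A flat,
#' individually significant alpha across waves justifies pooling the waves
#' into one calibration.
#'
#' @param transitions an [extract_transitions()] result spanning at least
#'   three wave pairs.
#' @param quantity `"alpha"` (intercepts) or `"beta"` (slopes).
#' @return data.frame of per-wave estimates with attribute `trend`, a
#'   data.frame of per-transition trend slopes and p-values.
#' @export
per_wave_trend <- function(transitions, quantity = c("alpha", "beta")) {
  quantity <- match.arg(quantity)
  waves <- sort(unique(transitions$wave))
  if (length(waves) < 3) stop("need at least three wave pairs for a trend")
  pairs <- .transition_pairs()
  rows <- list()
  for (w in waves) {
    tw <- transitions[transitions$wave == w, , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      from <- pairs$from[i]; to <- pairs$to[i]
      points <- aggregate_by_neighbor_count(tw, from, to, to)
      if (nrow(points) == 0 || sum(points$n) < 10) next
      fit <- fit_wls(points)
      est <- if (quantity == "alpha") fit$intercept else fit$slope
      sef <- if (quantity == "alpha") fit$se_intercept else fit$se_slope
      pv <- if (quantity == "alpha") fit$p_intercept else fit$p_slope
      if (is.na(est)) next
      rows[[length(rows) + 1]] <-
        data.frame(wave = w, transition = paste0(from, "->", to),
                   estimate = est, se = sef, p_value = pv,
                   ci_lo = est - 1.96 * sef, ci_hi = est + 1.96 * sef)
    }
  }
  out <- do.call(rbind, rows)
  trend <- do.call(rbind, lapply(split(out, out$transition), function(d) {
    if (nrow(d) < 3 || any(!is.finite(d$se)) || any(d$se == 0))
      return(data.frame(transition = d$transition[1], slope = NA_real_,
                        p_value = NA_real_, n_waves = nrow(d)))
    fit <- lm(estimate ~ wave, data = d, weights = 1 / d$se^2)
    sm <- summary(fit)$coefficients
    data.frame(transition = d$transition[1], slope = sm["wave", 1],
               p_value = sm["wave", 4], n_waves = nrow(d))
  }))
  rownames(trend) <- NULL
  attr(out, "trend") <- trend
  out
}
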