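# Multiplicative intervention experiments on calibrated parameters.

# named rate sets: betas are (from, to, influencer) triples, alphas pairs
.named_rate_sets <- list(
  social_positive = list(beta = list(c("M", "A", "A"), c("H", "A", "A")),
                         alpha = list()),
  social_negative = list(beta = list(c("M", "H", "H"), c("A", "M", "H")),
                         alpha = list()),
  spontaneous_positive = list(beta = list(),
                              alpha = list(c("M", "A"), c("H", "A"),
                                           c("H", "M"))),
  spontaneous_negative = list(beta = list(),
                              alpha = list(c("A", "M"), c("A", "H"),
                                           c("M", "H"))))

#' Intervention specification
#'
#' Names the set of rates an intervention scales and the multiplier grid.
#' Predefined sets: `social_positive` (social rates toward abstinence,
#' beta_MA^A and beta_HA^A), `social_negative` (social rates toward
#' drinking, beta_MH^H and beta_AM^H), and the spontaneous analogues
#' (`spontaneous_positive`: alpha_MA, alpha_HA, alpha_HM;
#' `spontaneous_negative`: alpha_AM, alpha_AH, alpha_MH). A custom set may
#' list alpha pairs `c(from, to)` and beta triples `c(from, to, influencer)`.
#'
#' @param rate_set a predefined set name or a list with elements `alpha`
#'   and/or `beta` as above.
#' @param grid multiplier grid (> 0); must include the baseline 1.
#' @return list of class `intervention_spec`.
#' @export
intervention_spec <- function(rate_set = "social_negative",
                              grid = 2^seq(-2, 2, length.out = 7)) {
  if (is.character(rate_set)) {
    stopifnot(rate_set %in% names(.named_rate_sets))
    set <- .named_rate_sets[[rate_set]]
    name <- rate_set
  } else {
    set <- list(alpha = rate_set$alpha %||% list(),
                beta = rate_set$beta %||% list())
    name <- "custom"
  }
  stopifnot(all(grid > 0))
  if (!any(abs(grid - 1) < 1e-12)) stop("multiplier grid must include 1")
  structure(list(name = name, alpha = set$alpha, beta = set$beta,
                 grid = sort(grid)),
            class = "intervention_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiply a named set of rates
#'
#' Scales exactly the rates listed in `spec`; every other rate and all
#' significance metadata are left bit-identical.
#'
#' @param params an [amha_parameters()].
#' @param spec an [intervention_spec()].
#' @param multiplier positive scale factor.
#' @return a new [amha_parameters()].
#' @export
apply_multiplier <- function(params, spec, multiplier) {
  stopifnot(inherits(spec, "intervention_spec"), multiplier > 0)
  out <- params
  for (a in spec$alpha)
    out$alpha[a[1], a[2]] <- out$alpha[a[1], a[2]] * multiplier
  for (b in spec$beta)
    out$beta[b[1], b[2], b[3]] <- out$beta[b[1], b[2], b[3]] * multiplier
  out
}

#' Sweep an intervention multiplier and record endemic heavy drinking
#'
#' For every multiplier in the grid the named rates are scaled, the
#' network is simulated to the horizon, and the final heavy-drinker
#' fraction is summarised across replicates (mean and 2.5/97.5 percentile
#' interval). Replicates reuse the same seeds at every grid point (common
#' random numbers), so grid points differ only through the parameters. A
#' multiplier that pushes a per-step probability above 1 is flagged and
#' skipped, not fudged.
#'
#' @param network an igraph network.
#' @param states named initial state vector (see [simulate_amha()]).
#' @param params baseline [amha_parameters()].
#' @param spec an [intervention_spec()].
#' @param horizon_years,replicates,dt_years,seed simulation settings.
#' @param common_seeds reuse identical replicate seeds across grid points
#'   (default TRUE).
#' @return data.frame of class `intervention_sweep`: `multiplier`,
#'   `log2_multiplier`, `heavy_mean`, `heavy_lo`, `heavy_hi`, `skipped`.
#' @export
sweep_interventions <- function(network, states, params, spec,
                                horizon_years = 30, replicates = 33,
                                dt_years = 1, seed = 1, common_seeds = TRUE) {
  stopifnot(inherits(spec, "intervention_spec"))
  rows <- lapply(seq_along(spec$grid), function(i) {
    mult <- spec$grid[i]
    pm <- apply_multiplier(params, spec, mult)
    seed_i <- if (common_seeds) seed else seed + (i - 1L) * replicates
    res <- tryCatch({
      cfg <- sim_config(pm, horizon_years = horizon_years,
                        dt_years = dt_years, replicates = replicates,
                        seed = seed_i)
      sim <- simulate_amha(network, states, cfg)
      hfin <- sim$fractions[dim(sim$fractions)[1], "H", ]
      data.frame(multiplier = mult, log2_multiplier = log2(mult),
                 heavy_mean = mean(hfin),
                 heavy_lo = quantile(hfin, 0.025, names = FALSE),
                 heavy_hi = quantile(hfin, 0.975, names = FALSE),
                 skipped = FALSE)
    }, error = function(e) {
      warning(sprintf("multiplier %.3g skipped: %s", mult,
                      conditionMessage(e)))
      data.frame(multiplier = mult, log2_multiplier = log2(mult),
                 heavy_mean = NA_real_, heavy_lo = NA_real_,
                 heavy_hi = NA_real_, skipped = TRUE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("intervention_sweep", "data.frame")
  out
}

#' Compare increasing positive vs decreasing negative social influence
#'
#' Runs the `social_positive` rates at `factor` and the `social_negative`
#' rates at `1/factor` (equal "effort" on a log scale) and reports both
#' endemic heavy-drinker fractions with replicate intervals and their
#' difference. No verdict is hard-coded: which arm wins depends on the
#' calibrated parameters and the network.
#'
#' @param network,states,params as in [sweep_interventions()].
#' @param factor effort multiplier (> 1, applied up and down).
#' @param horizon_years,replicates,dt_years,seed simulation settings.
#' @return list of class `strategy_comparison` with `positive`, `negative`
#'   (each: multiplier, heavy_mean, heavy_lo, heavy_hi), `baseline`, and
#'   `difference` (positive minus negative arm mean).
#' @export
compare_strategies <- function(network, states, params, factor = 2,
                               horizon_years = 30, replicates = 33,
                               dt_years = 1, seed = 1) {
  stopifnot(factor >= 1)
  run_arm <- function(set, mult) {
    spec <- intervention_spec(set, grid = sort(unique(c(1, mult))))
    sw <- sweep_interventions(network, states, params, spec,
                              horizon_years = horizon_years,
                              replicates = replicates, dt_years = dt_years,
                              seed = seed)
    sw[abs(sw$multiplier - mult) < 1e-12, ]
  }
  pos <- run_arm("social_positive", factor)
  neg <- run_arm("social_negative", 1 / factor)
  base <- run_arm("social_positive", 1)    # multiplier 1 = baseline
  structure(list(positive = pos, negative = neg, baseline = base,
                 factor = factor,
                 difference = pos$heavy_mean - neg$heavy_mean),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("Strategy comparison at effort factor %g (endemic heavy fraction)\n",
              x$factor))
  cat(sprintf("  baseline              : %.3f [%.3f, %.3f]\n",
              x$baseline$heavy_mean, x$baseline$heavy_lo, x$baseline$heavy_hi))
  cat(sprintf("  social_positive x %-4g: %.3f [%.3f, %.3f]\n", x$factor,
              x$positive$heavy_mean, x$positive$heavy_lo, x$positive$heavy_hi))
  cat(sprintf("  social_negative / %-4g: %.3f [%.3f, %.3f]\n", x$factor,
              x$negative$heavy_mean, x$negative$heavy_lo, x$negative$heavy_hi))
  cat(sprintf("  difference (pos - neg): %+.3f\n", x$difference))
  invisible(x)
}
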