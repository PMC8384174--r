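# Plot-scale productivity: detection-corrected nest abundance times
# period nest survival, and its regression on habitat.

#' Expected successful nests per plot
#'
#' `N_hat * dsr^T`: detection-corrected nest abundance times the
#' probability of surviving the full `T`-day nest cycle.
#'
#' @param N_hat detection-corrected nest abundance (>= 0).
#' @param dsr daily survival in `[0, 1]`.
#' @param T exposure period in days (default 30).
#' @return expected number of successful nests.
#' @export
plot_productivity <- function(N_hat, dsr, T = 30) {
  stopifnot(all(N_hat >= 0), all(dsr >= 0), all(dsr <= 1))
  N_hat * dsr^T
}

#' Build the per-plot productivity table
#'
#' Combines the empirical-Bayes abundance predictions from the density
#' model with per-plot model-averaged daily survival into the
#' productivity of each plot.
#'
#' @param posterior a `dm_posterior` from [latent_posterior()].
#' @param dsr_avg per-plot model-averaged daily survival.
#' @param plot_covariates data frame of per-plot covariates (raw scale)
#'   carried along for regression.
#' @param T exposure period in days.
#' @return data frame of class `productivity_table` with `N_hat`
#'   (posterior mode), `N_mean` (posterior mean), `dsr`, `s_period`,
#'   `productivity`, and the covariates.
#' @export
productivity_table <- function(posterior, dsr_avg, plot_covariates = NULL,
                               T = 30) {
  stopifnot(length(dsr_avg) == length(posterior$mode))
  sT <- dsr_avg^T
  out <- data.frame(N_hat = posterior$mode, N_mean = posterior$mean,
                    dsr = dsr_avg, s_period = sT,
                    productivity = posterior$mode * sT)
  if (!is.null(plot_covariates))
    out <- cbind(out, as.data.frame(plot_covariates))
  class(out) <- c("productivity_table", "data.frame")
  out
}

#' Regress plot productivity on a habitat predictor
#'
#' Ordinary least squares of productivity on the predictor on its raw
#' measurement scale (so a biomass slope reads per kg/ha), with the
#' standardized-scale slope also reported. The effect is flagged
#' predictive only when the 95% confidence interval excludes zero AND
#' the adjusted r-squared exceeds `r2_threshold`.
#'
#' @param table a `productivity_table` (or any data frame with a
#'   `productivity` column).
#' @param predictor name of the predictor column.
#' @param r2_threshold adjusted r-squared needed for the predictive flag
#'   (default 0.6).
#' @return object of class `productivity_regression`: `slope`, `se`,
#'   `ci` (95%), `slope_std` (per predictor SD), `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_value`, `predictive`,
#'   `diagnostics` (Shapiro-Wilk p on residuals, residual-vs-fitted
#'   correlation of absolute residuals), and the underlying `lm` fit.
#' @export
productivity_regression <- function(table, predictor,
                                    r2_threshold = 0.6) {
  x <- table[[predictor]]
  if (is.null(x)) stop("predictor column not found: ", predictor)
  if (sd(x) == 0) stop("predictor has zero variance")
  if (nrow(table) < 3) stop("need at least 3 plots")
  fit <- lm(table$productivity ~ x)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  ci <- unname(confint(fit)[2, ])
  res <- residuals(fit)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000)
    tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
  else NA_real_
  het <- suppressWarnings(cor(abs(res), fitted(fit)))
  structure(list(
    slope = slope, se = se, ci = ci,
    slope_std = slope * sd(x), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    p_value = sm$coefficients[2, 4],
    predictive = (ci[1] > 0 || ci[2] < 0) &&
      sm$adj.r.squared > r2_threshold,
    diagnostics = list(shapiro_p = shapiro_p,
                       abs_resid_fitted_cor = het),
    lm = fit, predictor = predictor),
    class = "productivity_regression")
}

#' @export
print.productivity_regression <- function(x, ...) {
  cat("Productivity ~", x$predictor, "\n")
  cat(sprintf("  slope = %.6g (SE %.3g, 95%% CI %.6g to %.6g)\n",
              x$slope, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  r2 = %.3f (adjusted %.3f), P = %.3g\n",
              x$r_squared, x$adj_r_squared, x$p_value))
  cat("  predictive (CI excludes 0 and adj r2 > 0.6):",
      x$predictive, "\n")
  invisible(x)
}

#' Scale a per-plot effect to a management unit
#'
#' Translates a productivity slope (successful nests per plot per unit of
#' the predictor) into the expected change in successful nests across a
#' management unit: `slope * delta_predictor * unit_area / plot_area`.
#'
#' @param slope successful nests per plot per predictor unit.
#' @param delta_predictor change in the predictor (e.g. kg/ha of
#'   biomass).
#' @param unit_area_ha management-unit area in hectares.
#' @param plot_area_ha plot area in hectares (default 9).
#' @return expected change in successful nests over the unit.
#' @export
scale_to_management_unit <- function(slope, delta_predictor,
                                     unit_area_ha, plot_area_ha = 9) {
  stopifnot(unit_area_ha > 0, plot_area_ha > 0)
  slope * delta_predictor * unit_area_ha / plot_area_ha
}
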