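# End-to-end orchestration of the density -> survival -> productivity
# pipeline. Each stage returns a plain-list report fragment; all numbers
# in a report trace to a fitted object, and the seed is stamped in.

#' Serialize a fitted density model to a JSON report
#'
#' A plain-text summary of a `dm_fit`: estimates, SEs, log-likelihood,
#' parameter count, truncation bound, mixture, dynamics, and convergence
#' state.
#'
#' @param fit a `dm_fit`.
#' @param path output path.
#' @return invisibly, the report list.
#' @export
write_dm_report <- function(fit, path) {
  rep_ <- list(
    mixture = fit$mixture, dynamics = fit$dynamics,
    K = fit$parameters$K,
    estimates = as.list(fit$estimates), se = as.list(fit$se),
    gamma = fit$parameters$gamma, omega = fit$parameters$omega,
    log_likelihood = fit$log_likelihood, n_params = fit$n_params,
    convergence = fit$convergence, boundary = fit$boundary)
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep_)
}

#' Run the nest-density stage
#'
#' Standardizes covariates, compares the Poisson and negative-binomial
#' mixtures on a richly parameterized model (with a truncation-stability
#' check on each), estimates overdispersion by parametric bootstrap on
#' the chosen structure, runs backward stepwise selection, the closure
#' test, and empirical-Bayes abundance prediction.
#'
#' @param data a [nest_counts] object (raw-scale covariates).
#' @param detection_terms,density_terms candidate term lists for
#'   [backward_stepwise()] (names refer to standardized covariates).
#' @param B bootstrap replicates for the goodness-of-fit test.
#' @param seed RNG seed.
#' @param compare_mixtures also fit the negative-binomial mixture and
#'   report AICc support and K-stability for both (slower).
#' @return list report fragment: `standardization`, `mixture_comparison`
#'   (optional), `gof`, `stepwise`, `closure`, `posterior`,
#'   `best_fit`, `seed`.
#' @export
run_density <- function(data, detection_terms = list(),
                        density_terms = list(), B = 50, seed = 1,
                        compare_mixtures = FALSE) {
  all_terms <- unique(sub("\\^2$", "", unlist(c(detection_terms,
                                                density_terms))))
  std <- NULL
  if (!is.null(data$plot_covariates)) {
    plot_terms <- intersect(all_terms, names(data$plot_covariates))
    if (length(plot_terms)) {
      std <- standardize_covariates(data$plot_covariates[plot_terms])
      data$plot_covariates[plot_terms] <- std$data
    }
  }
  for (nm in intersect(all_terms, names(data$survey_covariates))) {
    cv <- data$survey_covariates[[nm]]
    obs <- data$observed_mask
    m <- mean(cv[obs]); s <- sd(cv[obs])
    if (s == 0) stop("constant survey covariate: ", nm)
    data$survey_covariates[[nm]] <- (cv - m) / s
  }

  mixture_comparison <- NULL
  if (compare_mixtures) {
    full_den <- unlist(density_terms); full_det <- unlist(detection_terms)
    fit_p <- fit_dm(data, full_den, full_det, "poisson", seed = seed)
    fit_nb <- tryCatch(
      fit_dm(data, full_den, full_det, "negbin", seed = seed),
      error = function(e) NULL)
    n_eff <- nrow(data$y)
    if (!is.null(fit_nb)) {
      crit <- c(poisson = aicc(fit_p$log_likelihood, fit_p$n_params,
                               n_eff),
                negbin = aicc(fit_nb$log_likelihood, fit_nb$n_params,
                              n_eff))
      aw <- akaike_weights(crit)
      mixture_comparison <- list(
        criteria = crit, weights = setNames(aw$weight, names(crit)),
        alpha = fit_nb$parameters$alpha,
        K_stability = list(poisson = check_K_stability(fit_p),
                           negbin = check_K_stability(fit_nb)))
    }
  }

  step <- backward_stepwise(data, detection_terms, density_terms,
                            mixture = "poisson")
  gof <- parametric_bootstrap_gof(step$best_fit, B = B, seed = seed)
  # re-rank the visited models under QAICc with the estimated c-hat
  step2 <- backward_stepwise(data, step$detection_terms,
                             step$density_terms, mixture = "poisson",
                             c_hat = gof$c_hat)
  closure <- closure_test(step$best_fit)
  post <- latent_posterior(step$best_fit)
  list(standardization = std, mixture_comparison = mixture_comparison,
       gof = gof, stepwise = step, closure = closure, posterior = post,
       best_fit = step$best_fit,
       mean_detection = mean(step$best_fit$p_hat[data$observed_mask]),
       seed = seed)
}

#' Run the nest-survival stage
#'
#' Standardizes the covariate columns used by the candidate sets, runs
#' the three-tier evaluation, and reports the constant-model daily
#' survival with its full-period extrapolation.
#'
#' @param records a [nest_records] data frame (raw-scale covariates).
#' @param nest_terms,plot_terms candidate lists for
#'   [tiered_evaluation()].
#' @param T period length in days for [period_survival()].
#' @return list report fragment: `tiers`, `null_dsr` (estimate, se),
#'   `period` (estimate, se), `apparent_success`, `standardization`.
#' @export
run_survival <- function(records, nest_terms = list(),
                         plot_terms = list(), T = 30) {
  if (!nrow(records))
    return(list(tiers = NULL, null_dsr = NULL, period = NULL,
                apparent_success = NA_real_, standardization = NULL,
                note = "no encounter records"))
  terms <- setdiff(unique(unlist(c(nest_terms, plot_terms))), "year")
  std <- NULL
  terms <- intersect(terms, names(records))
  if (length(terms)) {
    std <- standardize_covariates(records[terms])
    records[terms] <- std$data
  }
  tiers <- tiered_evaluation(records, nest_terms, plot_terms)
  null_fit <- fit_dsr(records, character())
  per <- period_survival(null_fit$dsr_null, null_fit$dsr_null *
                           (1 - null_fit$dsr_null) * null_fit$se[1], T)
  list(tiers = tiers, null_fit = null_fit,
       null_dsr = list(estimate = unname(null_fit$dsr_null),
                       se = unname(null_fit$dsr_null *
                                     (1 - null_fit$dsr_null) *
                                     null_fit$se[1])),
       period = per, apparent_success = apparent_success(records),
       standardization = std, T = T)
}

#' Run the productivity stage
#'
#' Combines the density fragment's empirical-Bayes abundance with
#' per-plot model-averaged daily survival from the survival fragment's
#' plot-scale tier, regresses productivity on a habitat predictor, and
#' restates the slope at management scale.
#'
#' @param density_fragment result of [run_density()].
#' @param survival_fragment result of [run_survival()].
#' @param plot_covariates raw-scale per-plot covariates (one row per
#'   plot, ordered as the count data).
#' @param predictor name of the regression predictor (default
#'   `"biomass"`).
#' @param T period length in days.
#' @return list report: `table` (productivity_table), `regression`,
#'   `per_100_units`, `management_example` (1000-ha unit, 1000-unit
#'   predictor change).
#' @export
run_productivity <- function(density_fragment, survival_fragment,
                             plot_covariates, predictor = "biomass",
                             T = 30) {
  if (is.null(density_fragment$posterior))
    stop("density fragment is missing its latent posterior")
  if (is.null(survival_fragment$tiers))
    stop("survival fragment is missing its model tables (no records?)")
  std <- survival_fragment$standardization
  plot_std <- as.data.frame(plot_covariates)
  if (!is.null(std)) {
    for (nm in intersect(names(plot_std), names(std$center)))
      plot_std[[nm]] <- (plot_std[[nm]] - std$center[[nm]]) /
        std$scale[[nm]]
  }
  tier <- survival_fragment$tiers$plot
  preds <- vapply(tier$fits, function(f)
    predict(f, plot_std)$dsr, numeric(nrow(plot_std)))
  ses <- vapply(tier$fits, function(f)
    predict(f, plot_std)$se, numeric(nrow(plot_std)))
  ses[is.na(ses)] <- 0
  avg <- model_average_predictions(t(preds), t(ses), tier$table$weight)
  tab <- productivity_table(density_fragment$posterior, avg$estimate,
                            plot_covariates, T = T)
  reg <- productivity_regression(tab, predictor)
  list(table = tab, regression = reg,
       per_100_units = reg$slope * 100,
       management_example = scale_to_management_unit(
         reg$slope, delta_predictor = 1000, unit_area_ha = 1000),
       dsr_avg = avg)
}
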