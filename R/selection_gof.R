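# Information-criterion machinery: AICc/QAICc, Akaike weights,
# parametric-bootstrap goodness of fit with c-hat, SE inflation,
# backward stepwise search, and model-averaged prediction.

#' Small-sample information criteria
#'
#' `aicc` is AIC with the finite-sample correction; `qaicc` divides the
#' log-likelihood by an overdispersion factor `c_hat` and counts one
#' extra parameter for `c_hat` itself whenever `c_hat > 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param K number of estimated parameters (before the `c_hat` parameter).
#' @param n effective sample size; must exceed `K + 1`.
#' @param c_hat variance inflation factor (values below 1 are clamped
#'   to 1).
#' @return the criterion value.
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) stop("effective sample size must exceed K + 1")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' @rdname aicc
#' @export
qaicc <- function(loglik, K, n, c_hat = 1) {
  c_hat <- max(c_hat, 1)
  if (c_hat > 1) K <- K + 1  # c_hat counts as an estimated parameter
  if (n <= K + 1) stop("effective sample size must exceed K + 1")
  -2 * loglik / c_hat + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike differences and weights
#'
#' @param criteria numeric vector of criterion values (AICc or QAICc).
#' @return data frame with `delta` and `weight`, ordered as the input;
#'   weights sum to one and the best model has `delta = 0`.
#' @export
akaike_weights <- function(criteria) {
  if (!length(criteria)) stop("need at least one model")
  delta <- criteria - min(criteria)
  w <- exp(-delta / 2)
  data.frame(delta = delta, weight = w / sum(w))
}

#' Inflate a standard error for overdispersion
#'
#' @param se standard error(s).
#' @param c_hat variance inflation factor; values below 1 are clamped to 1
#'   (standard quasi-likelihood practice).
#' @return `se * sqrt(max(c_hat, 1))`.
#' @export
inflate_se <- function(se, c_hat) se * sqrt(max(c_hat, 1))

#' Wald non-informative-effect screen
#'
#' An effect is considered non-informative when its overdispersion-
#' inflated Wald 95% interval contains zero.
#'
#' @param coefficient point estimate.
#' @param se its standard error.
#' @param c_hat variance inflation factor.
#' @param lower,upper alternatively, a pre-computed interval.
#' @return `TRUE` when the interval contains 0.
#' @export
noninformative_check <- function(coefficient, se = NULL, c_hat = 1,
                                 lower = NULL, upper = NULL) {
  if (is.null(lower) || is.null(upper)) {
    se <- inflate_se(se, c_hat)
    lower <- coefficient - 1.96 * se
    upper <- coefficient + 1.96 * se
  }
  lower <= 0 && upper >= 0
}

# Expected counts under a fitted open N-mixture model:
# E[y_it] = p_it * E[N_it], with E[N_1] = lambda and
# E[N_t] = omega * E[N_{t-1}] + gamma.
.dm_expected_counts <- function(fit) {
  M <- nrow(fit$data$y); T_ <- ncol(fit$data$y)
  EN <- matrix(0, M, T_)
  EN[, 1] <- fit$lambda_hat
  om <- fit$parameters$omega; ga <- fit$parameters$gamma
  if (T_ > 1) for (t in 2:T_) EN[, t] <- om * EN[, t - 1] + ga
  EN * fit$p_hat
}

# Pearson-type chi-square over surveyed (plot, occasion) cells, with a
# floor on tiny expectations so near-zero detection cannot explode it.
.dm_chisq <- function(fit, eps = 1e-6) {
  E <- .dm_expected_counts(fit)
  mask <- fit$data$observed_mask
  sum(((fit$data$y[mask] - E[mask])^2) / pmax(E[mask], eps))
}

#' Simulate replicated counts from a fitted model
#'
#' Parametric simulation of a new count dataset from a `dm_fit`,
#' preserving the observed missing-occasion mask and all covariates.
#'
#' @param fit a `dm_fit`.
#' @return a [nest_counts] object.
#' @export
simulate_from_fit <- function(fit) {
  M <- nrow(fit$data$y); T_ <- ncol(fit$data$y)
  lam <- fit$lambda_hat; p <- fit$p_hat
  om <- fit$parameters$omega; ga <- fit$parameters$gamma
  if (identical(fit$mixture, "negbin")) {
    N <- rnbinom(M, size = fit$parameters$alpha, mu = lam)
  } else {
    N <- rpois(M, lam)
  }
  y <- matrix(0L, M, T_)
  for (t in seq_len(T_)) {
    if (t > 1) N <- rbinom(M, N, om) + rpois(M, ga)
    y[, t] <- rbinom(M, N, p[, t])
  }
  y[!fit$data$observed_mask] <- NA_integer_
  nest_counts(y, fit$data$observed_mask, fit$data$plot_ids,
              fit$data$survey_covariates, fit$data$plot_covariates)
}

#' Parametric-bootstrap goodness of fit and overdispersion factor
#'
#' The observed Pearson chi-square statistic is compared against its
#' distribution under the fitted model: `B` datasets are simulated from
#' the fit (same design, same missing occasions), each is refit with the
#' same model structure, and the statistic recomputed. The variance
#' inflation factor is `c_hat = chisq_obs / mean(chisq_boot)` and the
#' goodness-of-fit p-value is the proportion of bootstrap statistics at
#' or above the observed one. Bootstrap refits that fail are excluded and
#' counted.
#'
#' @param fit a `dm_fit`.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @param eps floor applied to expected counts inside the statistic.
#' @return object of class `gof_report`: `chisq_observed`,
#'   `chisq_boot` (vector), `c_hat`, `p_value`, `n_failed`.
#' @export
parametric_bootstrap_gof <- function(fit, B = 100, seed = 1, eps = 1e-6) {
  stopifnot(B >= 1)
  set.seed(seed)
  obs <- .dm_chisq(fit, eps)
  boot <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(B)) {
    sim <- simulate_from_fit(fit)
    refit <- tryCatch(
      fit_dm(sim, fit$density_terms, fit$detection_terms, fit$mixture,
             fit$dynamics, K = fit$parameters$K, n_starts = 1,
             hessian = FALSE),
      error = function(e) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    boot <- c(boot, .dm_chisq(refit, eps))
  }
  if (!length(boot)) stop("all bootstrap refits failed")
  structure(list(chisq_observed = obs, chisq_boot = boot,
                 c_hat = obs / mean(boot),
                 p_value = mean(boot >= obs),
                 n_failed = n_failed, B = B),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat("Parametric-bootstrap goodness of fit (B =", x$B, ")\n")
  cat(sprintf("  chisq = %.2f, c-hat = %.3f, P = %.3f\n",
              x$chisq_observed, x$c_hat, x$p_value))
  if (x$n_failed) cat("  failed refits excluded:", x$n_failed, "\n")
  invisible(x)
}

# Build a model-selection table from a list of dm_fit objects.
.dm_model_table <- function(fits, labels, n_eff, c_hat = 1) {
  crit <- vapply(fits, function(f)
    qaicc(f$log_likelihood, f$n_params, n_eff, c_hat), numeric(1))
  aw <- akaike_weights(crit)
  tab <- data.frame(model = labels,
                    K = vapply(fits, `[[`, numeric(1), "n_params"),
                    loglik = vapply(fits, `[[`, numeric(1),
                                    "log_likelihood"),
                    criterion = crit, delta = aw$delta, weight = aw$weight,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$delta), ]
  rownames(tab) <- NULL
  tab
}

#' Backward stepwise model selection for the density model
#'
#' Stage 1 holds the density structure at the full model and drops
#' detection terms one at a time, keeping the best-criterion submodel
#' until no single drop improves the criterion; stage 2 fixes detection
#' at the stage-1 winner and repeats for the density terms. Ties are
#' broken toward fewer parameters. Models within `delta <= 2` of the best
#' are marked parsimonious.
#'
#' @param data a [nest_counts] object with standardized covariates.
#' @param detection_terms,density_terms full candidate term lists. An
#'   entry may be a character vector (e.g. `c("forb", "forb^2")`) dropped
#'   as a unit.
#' @param mixture,dynamics,K passed to [fit_dm()].
#' @param c_hat overdispersion factor for QAICc.
#' @param n_eff effective sample size for the criterion; defaults to the
#'   number of plots.
#' @return object of class `stepwise_result`: `table` (all visited models
#'   ranked, with a `parsimonious` flag), `detection_terms`,
#'   `density_terms` (the selected sets), `best_fit`, `n_failed`.
#' @export
backward_stepwise <- function(data, detection_terms = list(),
                              density_terms = list(),
                              mixture = "poisson", dynamics = "open",
                              K = NULL, c_hat = 1, n_eff = NULL) {
  if (is.null(n_eff)) n_eff <- nrow(data$y)
  detection_terms <- lapply(detection_terms, as.character)
  density_terms <- lapply(density_terms, as.character)
  n_failed <- 0L
  fits <- list(); labels <- character(); keys <- character()

  label_of <- function(det, den) {
    paste0("p(", if (length(det)) paste(unlist(det), collapse = "+")
           else ".", ") lambda(",
           if (length(den)) paste(unlist(den), collapse = "+") else ".",
           ")")
  }
  fit_once <- function(det, den) {
    key <- label_of(det, den)
    hit <- match(key, keys)
    if (!is.na(hit)) return(fits[[hit]])
    f <- tryCatch(
      fit_dm(data, unlist(den), unlist(det), mixture, dynamics, K = K,
             n_starts = 1),
      error = function(e) NULL)
    if (is.null(f)) { n_failed <<- n_failed + 1L; return(NULL) }
    fits[[length(fits) + 1L]] <<- f
    labels[length(labels) + 1L] <<- key
    keys[length(keys) + 1L] <<- key
    f
  }
  crit_of <- function(f) {
    if (is.null(f)) return(Inf)
    qaicc(f$log_likelihood, f$n_params, n_eff, c_hat)
  }
  # one backward pass over `terms`, the other model component held fixed
  prune <- function(terms, fixed, stage) {
    current <- terms
    f <- if (stage == "detection") fit_once(current, fixed) else
      fit_once(fixed, current)
    best_c <- crit_of(f)
    repeat {
      if (!length(current)) break
      cand <- lapply(seq_along(current), function(j) current[-j])
      cc <- vapply(cand, function(tm) {
        f2 <- if (stage == "detection") fit_once(tm, fixed) else
          fit_once(fixed, tm)
        crit_of(f2)
      }, numeric(1))
      j <- which.min(cc)
      # ties toward fewer parameters: accept a drop that does not worsen
      if (cc[j] <= best_c) {
        current <- cand[[j]]
        best_c <- cc[j]
      } else break
    }
    current
  }

  det_sel <- prune(detection_terms, density_terms, "detection")
  den_sel <- prune(density_terms, det_sel, "density")
  best <- fit_once(det_sel, den_sel)

  tab <- .dm_model_table(fits, labels, n_eff, c_hat)
  tab$parsimonious <- tab$delta <= 2
  structure(list(table = tab, detection_terms = det_sel,
                 density_terms = den_sel, best_fit = best,
                 n_failed = n_failed),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Backward stepwise selection (", nrow(x$table), " models visited)\n",
      sep = "")
  print(head(x$table, 10), digits = 5)
  if (x$n_failed) cat("  candidate fits failed:", x$n_failed, "\n")
  invisible(x)
}

#' Model-averaged predictions with unconditional SE
#'
#' Weighted average of per-model predictions with the standard
#' unconditional variance that adds the between-model spread to the
#' within-model variance.
#'
#' @param predictions matrix, models x targets (or a vector for a single
#'   target), of per-model point predictions.
#' @param ses matrix or vector of matching standard errors.
#' @param weights model weights; must sum to 1 (tolerance 1e-6).
#' @return list with `estimate` and `se`, each of length `n targets`.
#' @export
model_average_predictions <- function(predictions, ses, weights) {
  if (is.vector(predictions)) predictions <- matrix(predictions, ncol = 1)
  if (is.vector(ses)) ses <- matrix(ses, ncol = 1)
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  est <- drop(crossprod(predictions, weights))
  dev2 <- sweep(predictions, 2, est, "-")^2
  vr <- drop(crossprod(ses^2 + dev2, weights))
  list(estimate = est, se = sqrt(vr))
}

#' Export a model-selection table as delimited text
#'
#' @param table a data frame as produced by the selection routines.
#' @param path output path.
#' @export
write_model_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}
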