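# Daily nest-survival (DSR) exposure likelihood. Each nest contributes
# survival over its known-active interval [first_found, last_active) and,
# for failures, the probability of dying somewhere in the uncertainty
# window (last_active, last_checked].

#' Daily survival rate from a linear predictor
#'
#' Inverse-logit of `x' beta`. Covariates must be on the same
#' (standardized) scale as the fit that produced `beta`.
#'
#' @param X design matrix (or vector for one nest), intercept included.
#' @param beta coefficient vector on the logit scale.
#' @return daily survival probabilities in `(0, 1)`.
#' @export
dsr <- function(X, beta) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  plogis(drop(X %*% beta))
}

#' Per-nest exposure log-likelihood
#'
#' With constant daily survival `s` for a nest found on day `f`, last
#' seen active on day `a`, and last checked on day `c`:
#' successes contribute `(a - f) log s`; failures additionally contribute
#' `log(1 - s^(c - a))`, the probability of failing on one of the
#' `c - a` days of the uncertainty window (equal to the geometric sum
#' over the latent failure day).
#'
#' @param s daily survival, one value per nest.
#' @param first_found,last_active,last_checked integer day indices.
#' @param fate `"success"` or `"failure"` per nest.
#' @return vector of per-nest log-likelihood contributions.
#' @export
nest_loglik <- function(s, first_found, last_active, last_checked, fate) {
  surv_days <- last_active - first_found
  ll <- surv_days * log(s)
  fail <- fate == "failure"
  if (any(fail)) {
    w <- last_checked[fail] - last_active[fail]
    if (any(w <= 0))
      stop("failure records need last_checked > last_active")
    ll[fail] <- ll[fail] + log(1 - s[fail]^w)
  }
  ll
}

#' Fit a daily nest-survival model
#'
#' Maximizes the summed exposure log-likelihood over nests, with the
#' daily survival of each nest a logit-linear function of its (constant)
#' covariates. The criterion effective sample size is total exposure
#' days, `sum(last_checked - first_found)`.
#'
#' @param records a [nest_records] data frame; covariate columns should
#'   be standardized.
#' @param terms character vector of covariate column names (may include
#'   `"year"`, entered as a two-level indicator of the later year).
#' @return object of class `dsr_fit`: `beta`, `se`, `covariance`,
#'   `log_likelihood`, `n_params`, `effective_n`, `dsr_null` (daily
#'   survival at covariate zero), `boundary`, `terms`.
#' @export
fit_dsr <- function(records, terms = character()) {
  if (!nrow(records)) stop("no encounter records")
  X <- matrix(1, nrow(records), 1 + length(terms))
  colnames(X) <- c("(Intercept)", terms)
  for (j in seq_along(terms)) {
    tm <- terms[j]
    if (tm == "year") {
      yr <- records$year
      X[, j + 1] <- as.numeric(yr == sort(unique(yr))[-1][1])
    } else {
      if (!tm %in% names(records))
        stop("unknown covariate in survival terms: ", tm)
      X[, j + 1] <- records[[tm]]
    }
  }
  exposure <- records$last_checked - records$first_found
  if (all(exposure == 0)) stop("no positive exposure in records")
  nll <- function(beta) {
    if (any(abs(beta) > 50)) return(1e10)
    s <- dsr(X, beta)
    v <- -sum(nest_loglik(s, records$first_found, records$last_active,
                          records$last_checked, records$fate))
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(qlogis(0.9), rep(0, length(terms)))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  hess <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  covv <- if (is.null(hess)) NULL else
    tryCatch(solve(hess), error = function(e) NULL)
  boundary <- FALSE
  if (!is.null(covv) && (any(!is.finite(covv)) || any(diag(covv) < 0)))
    covv <- NULL
  if (is.null(covv) || abs(opt$par[1]) > 12) boundary <- TRUE
  beta <- setNames(opt$par, colnames(X))
  se <- if (is.null(covv)) rep(NA_real_, length(beta)) else sqrt(diag(covv))
  names(se) <- names(beta)
  structure(list(beta = beta, se = se, covariance = covv,
                 log_likelihood = -opt$value, n_params = length(beta),
                 effective_n = sum(exposure),
                 dsr_null = plogis(beta[[1]]), boundary = boundary,
                 terms = terms, X = X, records = records),
            class = "dsr_fit")
}

#' @export
print.dsr_fit <- function(x, ...) {
  cat("Daily nest-survival model (", x$n_params, " parameters, ",
      x$effective_n, " exposure days)\n", sep = "")
  print(round(cbind(Estimate = x$beta, SE = x$se), 4))
  cat("  DSR at covariate means:", round(x$dsr_null, 4), "\n")
  if (x$boundary) cat("  NOTE: boundary warning\n")
  invisible(x)
}

#' Predict daily survival for new covariates
#'
#' @param object a `dsr_fit`.
#' @param newdata data frame with the model's covariate columns
#'   (standardized scale); `year` defaults to the reference year when
#'   absent.
#' @param ... unused.
#' @return data frame with `dsr` and delta-method `se`.
#' @export
predict.dsr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$X
  } else {
    newdata <- as.data.frame(newdata)
    X <- matrix(1, nrow(newdata), object$n_params)
    for (j in seq_along(object$terms)) {
      tm <- object$terms[j]
      X[, j + 1] <- if (tm %in% names(newdata)) newdata[[tm]] else 0
    }
  }
  eta <- drop(X %*% object$beta)
  s <- plogis(eta)
  if (!is.null(object$covariance)) {
    se_eta <- sqrt(pmax(rowSums((X %*% object$covariance) * X), 0))
    se <- s * (1 - s) * se_eta
  } else se <- rep(NA_real_, length(s))
  data.frame(dsr = s, se = se)
}

#' Period survival from a daily rate
#'
#' Probability a nest survives a `T`-day exposure period, `s^T`, with the
#' delta-method standard error `T s^(T-1) se(s)`.
#'
#' @param dsr_hat estimated daily survival in `(0, 1)`.
#' @param se its standard error.
#' @param T period length in days (default 30, the full nest cycle).
#' @return list with `estimate` and `se`.
#' @export
period_survival <- function(dsr_hat, se = 0, T = 30) {
  stopifnot(T >= 1, all(dsr_hat >= 0), all(dsr_hat <= 1))
  list(estimate = dsr_hat^T, se = T * dsr_hat^(T - 1) * se)
}

#' Apparent nest success
#'
#' Fraction of monitored nests that fledged. Biased upward relative to
#' period survival because nests enter the sample only after surviving to
#' discovery.
#'
#' @param records a [nest_records] data frame, or pass counts directly.
#' @param n_success,n_total direct counts, used when `records` is `NULL`.
#' @return proportion in `[0, 1]`.
#' @export
apparent_success <- function(records = NULL, n_success = NULL,
                             n_total = NULL) {
  if (!is.null(records)) {
    n_success <- sum(records$fate == "success")
    n_total <- nrow(records)
  }
  n_success / n_total
}

#' Tiered candidate-set evaluation for nest survival
#'
#' Evaluates AICc candidate sets at three spatial tiers: covariates
#' measured at the nest site, covariates at the plot scale (including any
#' per-plot SD columns), and a multi-scale set combining the supported
#' (`delta <= 2`) terms of the first two tiers. Every tier includes the
#' null and year-only models. Entries in a tier's term list may be
#' character vectors evaluated as one model.
#'
#' @param records a [nest_records] data frame with standardized covariate
#'   columns and a `year` column.
#' @param nest_terms,plot_terms lists of candidate terms for the two
#'   scales.
#' @param with_year also evaluate each candidate with a year effect
#'   added.
#' @return list of class `tiered_dsr` with elements `nest`, `plot`,
#'   `multi`, each a list holding `table` (model, K, loglik, criterion,
#'   delta, weight) and `fits`.
#' @export
tiered_evaluation <- function(records, nest_terms = list(),
                              plot_terms = list(), with_year = TRUE) {
  has_year <- "year" %in% names(records) &&
    length(unique(records$year)) > 1
  eval_tier <- function(term_list) {
    cands <- list("null" = character())
    if (has_year) cands[["year"]] <- "year"
    for (tm in term_list) {
      tm <- as.character(tm)
      cands[[paste(tm, collapse = "+")]] <- tm
      if (has_year && with_year)
        cands[[paste(c("year", tm), collapse = "+")]] <- c("year", tm)
    }
    fits <- lapply(cands, function(tm) fit_dsr(records, tm))
    n_eff <- fits[[1]]$effective_n
    crit <- vapply(fits, function(f)
      aicc(f$log_likelihood, f$n_params, n_eff), numeric(1))
    aw <- akaike_weights(crit)
    tab <- data.frame(model = names(cands),
                      K = vapply(fits, `[[`, numeric(1), "n_params"),
                      loglik = vapply(fits, `[[`, numeric(1),
                                      "log_likelihood"),
                      criterion = crit, delta = aw$delta,
                      weight = aw$weight, stringsAsFactors = FALSE)
    ord <- order(tab$delta)
    list(table = tab[ord, ], fits = fits[ord])
  }
  nest_res <- eval_tier(nest_terms)
  plot_res <- eval_tier(plot_terms)
  supported <- function(res, term_list) {
    top <- res$table$model[res$table$delta <= 2]
    keep <- unique(unlist(lapply(term_list, function(tm)
      if (any(vapply(top, function(m)
        all(tm %in% strsplit(m, "\\+")[[1]]), logical(1)))) tm)))
    setdiff(keep, "year")
  }
  multi_terms <- unique(c(supported(nest_res, nest_terms),
                          supported(plot_res, plot_terms)))
  multi_list <- if (length(multi_terms)) {
    c(as.list(multi_terms),
      if (length(multi_terms) > 1) list(multi_terms))
  } else list()
  multi_res <- eval_tier(multi_list)
  structure(list(nest = nest_res, plot = plot_res, multi = multi_res),
            class = "tiered_dsr")
}
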