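# Open-population N-mixture model for replicated nest counts.
# Latent abundance N_it on {0..K}; N_i1 ~ Poisson(lambda_i) or
# NegBin(mean lambda_i, size alpha); N_it = Binomial(N_i,t-1, omega) +
# Poisson(gamma); y_it ~ Binomial(N_it, p_it). lambda on the log link,
# p on the logit link, gamma/omega as unconstrained log/logit scalars.

#' Initial abundance pmf
#'
#' Probability mass of the initial latent nest abundance on `{0..K}` under
#' the Poisson or negative-binomial mixture. The vector is the pmf
#' truncated at `K`; the truncation mass is deliberately not renormalized
#' away (it is reported by [check_K_stability()]-style diagnostics).
#'
#' @param lambda expected initial abundance (> 0, or 0 for the degenerate
#'   point mass at zero).
#' @param K truncation bound for the latent abundance.
#' @param mixture `"poisson"` or `"negbin"`.
#' @param alpha negative-binomial dispersion (size); required iff
#'   `mixture = "negbin"`.
#' @return numeric vector of length `K + 1`.
#' @export
initial_pmf <- function(lambda, K, mixture = c("poisson", "negbin"),
                        alpha = NULL) {
  mixture <- match.arg(mixture)
  if (K < 0) stop("K must be >= 0")
  if (lambda < 0) stop("lambda must be >= 0")
  if (mixture == "negbin") {
    if (is.null(alpha) || alpha <= 0)
      stop("negbin mixture requires dispersion alpha > 0")
    dnbinom(0:K, size = alpha, mu = lambda)
  } else {
    if (!is.null(alpha)) stop("alpha is only used with the negbin mixture")
    dpois(0:K, lambda)
  }
}

#' Between-survey transition pmf
#'
#' Distribution of the next latent abundance given the previous one:
#' binomial survivors (probability `omega`) plus Poisson recruits (rate
#' `gamma`), truncated at `K`.
#'
#' @param m previous abundance, `0 <= m <= K`.
#' @param gamma recruitment rate (>= 0).
#' @param omega between-survey nest survival probability in `[0, 1]`.
#' @param K truncation bound.
#' @return numeric vector of length `K + 1`; sums to 1 minus the mass
#'   truncated above `K`.
#' @export
transition_pmf <- function(m, gamma, omega, K) {
  stopifnot(m >= 0, m <= K, gamma >= 0, omega >= 0, omega <= 1)
  cpp_dm_transition(K, gamma, omega)[m + 1, ]
}

# Build the M x T detection-probability and length-M lambda arrays from a
# parameter vector. Design matrices: Xl (M x pl) for log lambda, Xp
# ((M*T) x pp, row-major by occasion within plot) for logit p.
.dm_unpack <- function(par, Xl, Xp, M, T_, mixture) {
  pl <- ncol(Xl); pp <- ncol(Xp)
  beta_l <- par[seq_len(pl)]
  beta_p <- par[pl + seq_len(pp)]
  log_gamma <- par[pl + pp + 1]
  logit_omega <- par[pl + pp + 2]
  alpha <- if (mixture == "negbin") exp(par[pl + pp + 3]) else NULL
  lambda <- exp(drop(Xl %*% beta_l))
  p <- matrix(plogis(drop(Xp %*% beta_p)), M, T_)
  list(beta_lambda = beta_l, beta_p = beta_p, gamma = exp(log_gamma),
       omega = plogis(logit_omega), alpha = alpha, lambda = lambda, p = p)
}

#' Site log-likelihoods of the open N-mixture model
#'
#' Forward recursion over the latent abundance for each plot: initialize
#' with the initial pmf, multiply in the binomial detection term at each
#' surveyed occasion, and propagate through the survival/recruitment
#' transition between occasions. Unsurveyed occasions contribute no
#' detection term.
#'
#' @param y M x T integer count matrix.
#' @param observed_mask M x T logical matrix.
#' @param lambda length-M expected initial abundances.
#' @param p M x T detection probabilities.
#' @param gamma,omega dynamics parameters.
#' @param K truncation bound; must be at least `max(y)`.
#' @param mixture,alpha initial-distribution family, see [initial_pmf()].
#' @return length-M vector of per-plot log-likelihood contributions.
#' @export
dm_site_loglik <- function(y, observed_mask, lambda, p, gamma, omega, K,
                           mixture = "poisson", alpha = NULL) {
  y <- as.matrix(y)
  if (max(y[observed_mask]) > K) stop("K is below the maximum observed count")
  yy <- y; yy[!observed_mask] <- 0L
  storage.mode(yy) <- "integer"
  cpp_dm_site_loglik(yy, as.matrix(observed_mask), lambda, as.matrix(p),
                     gamma, omega, as.integer(K),
                     identical(mixture, "negbin"),
                     if (is.null(alpha)) 1.0 else alpha)
}

# Assemble a design matrix from covariate-name terms. Plot covariates are
# recycled across occasions for detection designs. A term "x^2" squares
# the (standardized) column "x".
.dm_design <- function(terms, plot_cov, survey_cov = NULL, M, T_ = NULL) {
  per_survey <- !is.null(T_)
  n <- if (per_survey) M * T_ else M
  X <- matrix(1, n, 1 + length(terms))
  colnames(X) <- c("(Intercept)", terms)
  for (j in seq_along(terms)) {
    tm <- terms[j]
    sq <- grepl("\\^2$", tm)
    base <- sub("\\^2$", "", tm)
    if (per_survey && !is.null(survey_cov) && base %in% names(survey_cov)) {
      v <- as.vector(survey_cov[[base]])
      v[is.na(v)] <- 0  # unobserved occasions: value is never used
    } else if (!is.null(plot_cov) && base %in% names(plot_cov)) {
      v <- plot_cov[[base]]
      if (per_survey) v <- rep(v, times = T_)
    } else {
      stop("unknown covariate in model terms: ", base)
    }
    X[, j + 1] <- if (sq) v^2 else v
  }
  X
}

#' Fit the open N-mixture nest-density model
#'
#' Maximizes the summed site log-likelihood by quasi-Newton (BFGS)
#' iteration on the unconstrained scale, from a moment-based start plus
#' optional seeded random restarts. Standard errors come from the inverse
#' of the numerically differentiated observed information.
#'
#' @param data a [nest_counts] object. Covariates referenced in the model
#'   terms should already be standardized.
#' @param density_terms,detection_terms character vectors of covariate
#'   names for log initial abundance and logit detection; a quadratic is
#'   written `"x^2"` and normally entered together with `"x"`.
#' @param mixture `"poisson"` (default) or `"negbin"`.
#' @param dynamics `"open"` estimates both recruitment and survival;
#'   `"no_recruitment"` fixes `gamma = 0` (declining-only nest
#'   population); `"closed"` fixes `gamma = 0, omega = 1`, the closed
#'   N-mixture special case.
#' @param K latent-abundance truncation bound; default max observed count
#'   plus 100.
#' @param n_starts number of optimizer starts (1 = moment start only;
#'   additional starts are seeded normal perturbations of it).
#' @param start optional full start vector overriding the moment start.
#' @param seed seed for the random restarts.
#' @param hessian compute the observed-information covariance (skipped
#'   for speed inside bootstrap refits).
#' @return an object of class `dm_fit` with elements `estimates`
#'   (named vector on the working scale), `parameters` (list with
#'   `beta_lambda`, `beta_p`, `gamma`, `omega`, `alpha`, `K`),
#'   `covariance`, `se`, `log_likelihood`, `n_params`, `convergence`,
#'   `boundary`, and the design information needed for prediction.
#' @export
fit_dm <- function(data, density_terms = character(),
                   detection_terms = character(),
                   mixture = c("poisson", "negbin"),
                   dynamics = c("open", "no_recruitment", "closed"),
                   K = NULL, n_starts = 1, start = NULL, seed = 1,
                   hessian = TRUE) {
  mixture <- match.arg(mixture)
  dynamics <- match.arg(dynamics)
  y <- data$y; mask <- data$observed_mask
  M <- nrow(y); T_ <- ncol(y)
  maxy <- max(y[mask])
  if (is.null(K)) K <- maxy + 100L
  if (K < maxy) stop("K must be at least the maximum observed count")
  Xl <- .dm_design(density_terms, data$plot_covariates, NULL, M)
  Xp <- .dm_design(detection_terms, data$plot_covariates,
                   data$survey_covariates, M, T_)
  pl <- ncol(Xl); pp <- ncol(Xp)
  npar <- pl + pp + 2L + (mixture == "negbin")
  # working-scale values pinning gamma ~ 0 and/or omega ~ 1
  fixed <- rep(NA_real_, npar)
  if (dynamics != "open") fixed[pl + pp + 1] <- -30      # gamma = 0
  if (dynamics == "closed") fixed[pl + pp + 2] <- 30     # omega = 1
  free <- which(is.na(fixed))

  full_par <- function(parfree) {
    par <- fixed
    par[free] <- parfree
    par
  }
  # pre-masked integer counts for the C++ forward recursion
  yy <- y; yy[!mask] <- 0L
  storage.mode(yy) <- "integer"
  if (max(yy) > K) stop("K must be at least the maximum observed count")
  nb <- mixture == "negbin"
  nll <- function(parfree) {
    par <- full_par(parfree)
    if (any(!is.finite(par))) return(1e10)
    u <- .dm_unpack(par, Xl, Xp, M, T_, mixture)
    ll <- cpp_dm_site_loglik(yy, mask, u$lambda, u$p, u$gamma, u$omega,
                             as.integer(K), nb,
                             if (nb) u$alpha else 1.0)
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }
  # box bounds on the working scale keep the latent states inside the
  # truncation and avoid cliffs in the quasi-Newton search
  lower <- rep(-20, npar); upper <- rep(20, npar)
  lower[seq_len(pl)] <- -10; upper[seq_len(pl)] <- 10
  lower <- lower[free]; upper <- upper[free]

  # moment start: lambda from mean count assuming p ~ 0.2
  mstart <- numeric(npar)
  mstart[1] <- log(max(mean(y[mask]), 0.01) / 0.2)
  mstart[pl + 1] <- qlogis(0.2)
  mstart[pl + pp + 1] <- log(0.05)       # log gamma
  mstart[pl + pp + 2] <- qlogis(0.8)     # logit omega
  if (mixture == "negbin") mstart[npar] <- log(1)
  mstart <- (if (is.null(start)) mstart else start)[free]
  starts <- list(mstart)
  if (n_starts > 1) {
    set.seed(seed)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- mstart + rnorm(length(free), 0, 0.5)
  }

  best <- NULL
  fails <- 0L
  for (s0 in starts) {
    opt <- tryCatch(
      optim(s0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt) || opt$value >= 1e10) { fails <- fails + 1L; next }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("open N-mixture fit failed to converge from all ", length(starts),
         " start(s)")

  hess <- if (hessian)
    tryCatch(optimHess(best$par, nll), error = function(e) NULL) else NULL
  covv <- NULL; boundary <- FALSE
  if (!is.null(hess)) {
    covv <- tryCatch(solve(hess), error = function(e) NULL)
    if (is.null(covv) || any(!is.finite(covv)) || any(diag(covv) < 0)) {
      covv <- NULL
    } else {
      covv <- (covv + t(covv)) / 2
    }
  }
  if (is.null(covv)) boundary <- TRUE

  parfull <- full_par(best$par)
  # boundary diagnostics: lambda collapsing to 0 or free dynamics at the
  # edge of the working scale
  if (parfull[1] < -9 ||
      (dynamics == "open" && abs(parfull[pl + pp + 2]) > 15))
    boundary <- TRUE

  u <- .dm_unpack(parfull, Xl, Xp, M, T_, mixture)
  if (dynamics != "open") u$gamma <- 0
  if (dynamics == "closed") u$omega <- 1
  nms <- c(paste0("lambda:", colnames(Xl)), paste0("p:", colnames(Xp)),
           "log_gamma", "logit_omega",
           if (mixture == "negbin") "log_alpha")
  estimates <- setNames(parfull, nms)
  se <- rep(NA_real_, npar)
  if (!is.null(covv)) se[free] <- sqrt(diag(covv))
  se[!is.na(fixed)] <- 0
  names(se) <- nms
  structure(list(
    estimates = estimates,
    parameters = list(beta_lambda = u$beta_lambda, beta_p = u$beta_p,
                      gamma = u$gamma, omega = u$omega, alpha = u$alpha,
                      K = K),
    covariance = covv, se = se,
    log_likelihood = -best$value, n_params = length(free),
    convergence = best$convergence, boundary = boundary,
    failed_starts = fails,
    density_terms = density_terms, detection_terms = detection_terms,
    mixture = mixture, dynamics = dynamics, data = data, Xl = Xl,
    Xp = Xp, lambda_hat = u$lambda, p_hat = u$p),
    class = "dm_fit")
}

#' @export
print.dm_fit <- function(x, ...) {
  cat("Open N-mixture nest-density model (", x$mixture, " mixture, K = ",
      x$parameters$K, ")\n", sep = "")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 6),
      " parameters:", x$n_params, "\n")
  est <- cbind(Estimate = x$estimates, SE = x$se)
  print(round(est, 4))
  cat("  gamma =", signif(x$parameters$gamma, 4),
      " omega =", signif(x$parameters$omega, 4), "\n")
  if (x$boundary) cat("  NOTE: boundary or identifiability warning\n")
  invisible(x)
}

#' Truncation-bound stability check
#'
#' Refits the model at increased truncation bounds and reports the largest
#' absolute change in any coefficient and in the log-likelihood. Unstable
#' coefficient trajectories under growing `K` were how the
#' negative-binomial mixture's identifiability pathology shows itself, so
#' this diagnostic is run routinely; it reports, it never throws.
#'
#' @param fit a `dm_fit`.
#' @param increments integer increments added to the fitted `K`.
#' @param tolerance flag "unstable" when any coefficient moves more than
#'   this (standardized scale).
#' @return list with per-increment coefficient deltas, `max_delta`,
#'   `loglik_delta`, and `stable`.
#' @export
check_K_stability <- function(fit, increments = c(20L, 50L),
                              tolerance = 0.01) {
  if (any(increments <= 0)) stop("increments must be positive")
  base_par <- fit$estimates
  rows <- lapply(increments, function(inc) {
    refit <- tryCatch(
      fit_dm(fit$data, fit$density_terms, fit$detection_terms,
             fit$mixture, fit$dynamics, K = fit$parameters$K + inc,
             n_starts = 1, start = unname(base_par)),
      error = function(e) NULL)
    if (is.null(refit))
      return(list(K = fit$parameters$K + inc, max_delta = NA_real_,
                  loglik_delta = NA_real_, failed = TRUE))
    list(K = refit$parameters$K,
         max_delta = max(abs(refit$estimates - base_par)),
         loglik_delta = refit$log_likelihood - fit$log_likelihood,
         failed = FALSE)
  })
  deltas <- vapply(rows, `[[`, numeric(1), "max_delta")
  list(K = fit$parameters$K, refits = rows,
       max_delta = suppressWarnings(max(deltas, na.rm = TRUE)),
       loglik_delta = max(abs(vapply(rows, function(r)
         ifelse(r$failed, NA_real_, r$loglik_delta), numeric(1))),
         na.rm = TRUE),
       stable = all(!is.na(deltas)) && all(deltas <= tolerance))
}

#' Closure test from the fitted dynamics
#'
#' The population of nests is closed over the survey window only if
#' recruitment is zero and between-survey survival is one. The average
#' percent change in nest numbers per survey interval is
#' `(omega + gamma - 1) * 100`; a negative value is a percent decrease
#' (e.g. omega = 0.87 with negligible gamma is a 13% decline). Closure is rejected when the Wald 95% interval for `gamma`
#' excludes 0 from above or the interval for `omega` excludes 1 from
#' below (delta-method intervals on the natural scale).
#'
#' @param fit a `dm_fit`, or `NULL` when supplying `gamma`/`omega`
#'   directly.
#' @param gamma,omega,se_gamma,se_omega direct natural-scale values,
#'   used when `fit` is `NULL` (SEs may be omitted, in which case the
#'   interval test is skipped and `closed` is `NA`).
#' @return list with `gamma_hat`, `omega_hat`, their SEs,
#'   `percent_change_per_interval` (negative = decline), and `closed`.
#' @export
closure_test <- function(fit = NULL, gamma = NULL, omega = NULL,
                         se_gamma = NULL, se_omega = NULL) {
  if (!is.null(fit)) {
    gamma <- fit$parameters$gamma
    omega <- fit$parameters$omega
    lg <- fit$se["log_gamma"]; lo <- fit$se["logit_omega"]
    se_gamma <- unname(gamma * lg)                 # delta from log scale
    se_omega <- unname(omega * (1 - omega) * lo)   # delta from logit scale
  }
  pct <- (omega + gamma - 1) * 100
  closed <- NA
  if (!is.null(se_gamma) && !is.null(se_omega) &&
      all(is.finite(c(se_gamma, se_omega)))) {
    gamma_lo <- gamma - 1.96 * se_gamma
    omega_hi <- omega + 1.96 * se_omega
    closed <- !(gamma_lo > 0 || omega_hi < 1)
  }
  list(gamma_hat = gamma, omega_hat = omega,
       se_gamma = se_gamma, se_omega = se_omega,
       percent_change_per_interval = pct, closed = closed)
}

#' Empirical-Bayes posterior of the latent nest abundance
#'
#' Per-plot posterior distribution of the latent abundance at each
#' occasion, conditional on the fitted parameters, via the
#' forward-backward construction. The point prediction of the occasion-1
#' abundance is the posterior mode, with ties broken toward the smaller
#' abundance (conservative).
#'
#' @param fit a `dm_fit`.
#' @return object of class `dm_posterior`: list with `posterior` (list of
#'   M matrices, `(K+1) x T`, columns summing to 1), `mode` (length-M
#'   integer, occasion-1 posterior mode), and `mean` (length-M
#'   posterior mean at occasion 1).
#' @export
latent_posterior <- function(fit) {
  y <- fit$data$y; mask <- fit$data$observed_mask
  M <- nrow(y); T_ <- ncol(y); K <- fit$parameters$K
  mode1 <- integer(M); mean1 <- numeric(M)
  posts <- vector("list", M)
  nb <- identical(fit$mixture, "negbin")
  alpha <- if (nb) fit$parameters$alpha else 1.0
  for (i in seq_len(M)) {
    yy <- y[i, ]; yy[!mask[i, ]] <- 0L
    fb <- cpp_dm_forward_backward(as.integer(yy), mask[i, ],
                                  fit$lambda_hat[i], fit$p_hat[i, ],
                                  fit$parameters$gamma,
                                  fit$parameters$omega,
                                  as.integer(K), nb, alpha)
    post <- fb$alpha * fb$beta
    post <- sweep(post, 2, colSums(post), "/")
    posts[[i]] <- post
    p1 <- post[, 1]
    mode1[i] <- which(p1 == max(p1))[1] - 1L  # ties -> smaller N
    mean1[i] <- sum((0:K) * p1)
  }
  structure(list(posterior = posts, mode = mode1, mean = mean1, K = K),
            class = "dm_posterior")
}

#' Predict expected initial nest abundance
#'
#' `lambda_hat = exp(x' beta)` per plot with delta-method standard errors;
#' intervals can be inflated by an overdispersion factor `c_hat`.
#'
#' @param fit a `dm_fit`.
#' @param newdata data frame of plot covariates on the same standardized
#'   scale as the fit; defaults to the fitting data.
#' @param c_hat variance inflation factor applied to the SEs (clamped at 1
#'   from below).
#' @return data frame with `lambda`, `se`, `lower`, `upper` (Wald 95%,
#'   log-scale construction).
#' @export
predict_density <- function(fit, newdata = NULL, c_hat = 1) {
  X <- if (is.null(newdata)) fit$Xl else
    .dm_design(fit$density_terms, as.data.frame(newdata), NULL,
               nrow(as.data.frame(newdata)))
  idx <- seq_len(ncol(fit$Xl))
  beta <- fit$parameters$beta_lambda
  eta <- drop(X %*% beta)
  lam <- exp(eta)
  infl <- sqrt(max(c_hat, 1))
  if (!is.null(fit$covariance)) {
    V <- fit$covariance[idx, idx, drop = FALSE]
    se_eta <- sqrt(pmax(rowSums((X %*% V) * X), 0)) * infl
  } else {
    se_eta <- rep(NA_real_, length(eta))
  }
  data.frame(lambda = lam, se = lam * se_eta,
             lower = exp(eta - 1.96 * se_eta),
             upper = exp(eta + 1.96 * se_eta))
}

#' Vertex of a fitted quadratic response
#'
#' For a response with linear and quadratic coefficients `b1 + b2 x^2`
#' (with `b2 < 0`), the covariate value maximizing the response is
#' `-b1 / (2 b2)`. Used to report, e.g., the forb cover or slope at which
#' predicted nest density peaks, on whichever covariate scale the
#' coefficients are given.
#'
#' @param b1,b2 linear and quadratic coefficients.
#' @return the stationary covariate value.
#' @export
quadratic_vertex <- function(b1, b2) {
  if (b2 == 0) stop("quadratic coefficient is zero; no vertex")
  -b1 / (2 * b2)
}
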