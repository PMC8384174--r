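# Synthetic-study generator. Emulates the sampling design the analysis
# assumes: M 9-ha plots surveyed 2-3 times inside a 30-day window,
# imperfect shrub-dependent nest detection, open nest dynamics between
# surveys, and daily nest survival with discovery conditional on a nest
# being active on its (uniform) search day.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the rest of the package is
#' tested against: 100 plots, 3 survey occasions 9 days apart (29% of
#' plots get only 2), mean initial nest abundance 2.65 per plot with the
#' fitted density structure (biomass effect -1.65 per SD, quadratic forb
#' and slope response curves peaking near 11% forb cover and 2.4
#' degrees), detection averaging 0.16 and declining 0.20 logits per
#' percent shrub cover, between-survey nest survival 0.87 with
#' negligible recruitment, and daily nest survival 0.93. Plot covariates
#' are drawn from a Gaussian copula with a strong (0.77) biomass-exotic
#' correlation.
#'
#' @param M number of plots.
#' @param T number of survey occasions.
#' @param interval_days days between occasions.
#' @param two_survey_frac share of plots with one fewer occasion.
#' @param lambda_mean mean initial nest abundance across plots. The
#'   density linear predictor is centred on the realized plots so this
#'   mean holds exactly in expectation whatever the covariate effects.
#' @param density_beta named vector of density effects on standardized
#'   plot covariates (log scale); default is the fitted biomass effect
#'   of -1.65 per SD.
#' @param density_quad named list of `c(linear, quadratic)` density
#'   effects on the raw percent (covers) or degree (slope) scale;
#'   defaults are the fitted forb and slope response curves.
#' @param p_intercept logit detection at zero shrub cover.
#' @param p_shrub_per_percent detection slope per percent shrub cover.
#' @param detection_beta named vector of extra detection effects on
#'   standardized survey covariates (logit scale).
#' @param gamma,omega between-survey recruitment rate and nest survival.
#' @param dsr daily nest survival at covariate means.
#' @param dsr_beta named vector of survival effects on standardized plot
#'   covariates (logit scale).
#' @param season_days length of the nesting season window for nest
#'   initiation.
#' @param nest_period_days days a nest must survive to fledge.
#' @param check_interval_days days between monitoring visits.
#' @param biomass_exotic_r target biomass-exotic correlation on the
#'   transformed (copula) scale.
#' @param mixture initial-abundance family: `"poisson"` (default) or
#'   `"negbin"` for overdispersed counts.
#' @param nb_alpha negative-binomial dispersion (size) when
#'   `mixture = "negbin"`; default the fitted 2.16.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(M = 100, T = 3, interval_days = 9,
                       two_survey_frac = 0.29,
                       lambda_mean = 2.65,
                       density_beta = c(biomass = -1.65),
                       density_quad = list(forb = c(0.49, -0.021),
                                           slope = c(0.34, -0.07)),
                       p_intercept = qlogis(0.38),
                       p_shrub_per_percent = -0.20,
                       detection_beta = numeric(),
                       gamma = 0, omega = 0.87,
                       dsr = 0.93, dsr_beta = numeric(),
                       season_days = 30, nest_period_days = 30,
                       check_interval_days = 3,
                       biomass_exotic_r = 0.77,
                       mixture = c("poisson", "negbin"),
                       nb_alpha = 2.16) {
  mixture <- match.arg(mixture)
  stopifnot(M >= 1, T >= 1, omega >= 0, omega <= 1, gamma >= 0,
            dsr > 0, dsr < 1, two_survey_frac >= 0, two_survey_frac <= 1,
            abs(biomass_exotic_r) <= 1, lambda_mean > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Expected initial abundance per plot: covariate effects (standardized
# linear terms plus raw-scale quadratic response curves), centred on the
# realized plots so the across-plot mean equals lambda_mean.
.sim_lambda <- function(config, covariates) {
  eta <- .std_effects(covariates, config$density_beta)
  for (nm in names(config$density_quad)) {
    b <- config$density_quad[[nm]]
    x <- covariates[[nm]]
    if (nm %in% c("forb", "shrub", "litter", "residual_grass", "exotic"))
      x <- x * 100  # coefficients are per percent cover
    eta <- eta + b[1] * x + b[2] * x^2
  }
  config$lambda_mean * exp(eta) / mean(exp(eta))
}

#' Simulate plot-scale vegetation covariates
#'
#' Multivariate normal on transformed scales (log for biomass and slope,
#' logit for proportional covers), back-transformed; biomass and exotic
#' cover share a latent correlation (default 0.77), all other pairs are
#' independent.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data frame with one row per plot: `biomass` (kg/ha),
#'   `biomass_sd`, `forb`, `shrub`, `litter`, `residual_grass`, `exotic`
#'   (proportions), `slope` (degrees).
#' @export
simulate_covariates <- function(config, seed = 1) {
  set.seed(seed)
  M <- config$M
  r <- config$biomass_exotic_r
  zb <- rnorm(M)
  ze <- r * zb + sqrt(1 - r^2) * rnorm(M)
  biomass <- exp(log(1200) + 0.40 * zb)
  exotic <- plogis(qlogis(0.15) + 0.8 * ze)
  data.frame(
    biomass = biomass,
    biomass_sd = biomass * 0.30 * exp(0.3 * rnorm(M)),
    forb = plogis(qlogis(0.08) + 0.5 * rnorm(M)),
    shrub = plogis(qlogis(0.06) + 0.5 * rnorm(M)),
    litter = plogis(qlogis(0.20) + 0.5 * rnorm(M)),
    residual_grass = plogis(qlogis(0.15) + 0.5 * rnorm(M)),
    exotic = exotic,
    slope = exp(log(2) + 0.6 * rnorm(M)))
}

# standardized columns used for the named effect vectors
.std_effects <- function(covariates, beta) {
  if (!length(beta)) return(numeric(nrow(covariates)))
  z <- scale(as.matrix(covariates[names(beta)]))
  drop(z %*% beta)
}

# per-(plot, occasion) detection probabilities and survey covariates
.sim_detection <- function(config, covariates, M, T_) {
  shrub_pct <- covariates$shrub * 100
  lp <- config$p_intercept + config$p_shrub_per_percent * shrub_pct
  p <- matrix(rep(lp, T_), M, T_)
  scov <- list(
    date = matrix(rep(1 + (seq_len(T_) - 1) * config$interval_days,
                      each = M), M, T_),
    time = matrix(sample(c(8, 18.5), M * T_, replace = TRUE), M, T_),
    wind = matrix(pmax(rnorm(M * T_, 10, 5), 0), M, T_),
    temp = matrix(rnorm(M * T_, 15, 5), M, T_),
    cloud = matrix(runif(M * T_, 0, 100), M, T_))
  for (nm in names(config$detection_beta)) {
    z <- (scov[[nm]] - mean(scov[[nm]])) / sd(scov[[nm]])
    p <- p + config$detection_beta[[nm]] * z
  }
  list(p = plogis(p), survey_covariates = scov)
}

#' Simulate replicated nest counts with known truth
#'
#' Generates the open N-mixture process: initial abundance Poisson in the
#' plot's expected density, binomial between-survey survival plus Poisson
#' recruits, and binomial detection of the nests present at each survey.
#' A seeded subset of plots (`two_survey_frac`) loses its final occasion.
#'
#' @param config a [sim_config()].
#' @param covariates plot covariates from [simulate_covariates()];
#'   generated if `NULL`.
#' @param seed RNG seed.
#' @return list with `data` (a [nest_counts]) and `truth` (list with
#'   `N` the M x T latent abundance matrix, `lambda`, `p`).
#' @export
simulate_counts <- function(config, covariates = NULL, seed = 1) {
  if (is.null(covariates)) covariates <- simulate_covariates(config, seed)
  set.seed(seed + 1L)
  M <- config$M; T_ <- config$T
  lambda <- .sim_lambda(config, covariates)
  det <- .sim_detection(config, covariates, M, T_)
  N <- matrix(0L, M, T_)
  y <- matrix(0L, M, T_)
  N[, 1] <- if (identical(config$mixture, "negbin"))
    rnbinom(M, size = config$nb_alpha, mu = lambda) else rpois(M, lambda)
  for (t in seq_len(T_)) {
    if (t > 1)
      N[, t] <- rbinom(M, N[, t - 1], config$omega) +
        rpois(M, config$gamma)
    y[, t] <- rbinom(M, N[, t], det$p[, t])
  }
  mask <- matrix(TRUE, M, T_)
  if (config$two_survey_frac > 0 && T_ > 1) {
    n2 <- round(config$two_survey_frac * M)
    if (n2 > 0) mask[sample(M, n2), T_] <- FALSE
  }
  y[!mask] <- NA_integer_
  data <- nest_counts(y, mask,
                      survey_covariates = det$survey_covariates,
                      plot_covariates = covariates)
  list(data = data, truth = list(N = N, lambda = lambda, p = det$p))
}

#' Simulate nest encounter histories with known truth
#'
#' Nests are initiated per plot (Poisson in the plot's expected density),
#' initiation days uniform over the season window, and survive each day
#' with the plot's daily survival rate for up to the full nest period. A
#' search day is drawn uniformly over the nest period; the nest enters
#' the monitored sample only if it is still active that day (this is what
#' makes apparent success exceed true period survival). Monitored nests
#' are then checked every `check_interval_days` days; the failure day is
#' only known to lie in the window between the last active check and the
#' first inactive one.
#'
#' @param config a [sim_config()].
#' @param covariates plot covariates; generated if `NULL`.
#' @param seed RNG seed.
#' @param n_nests optional total nest count override; nests are then
#'   spread over plots as evenly as possible.
#' @return list with `records` (a [nest_records] data frame of the
#'   discovered nests, with plot covariates attached) and `truth` (per
#'   plot: `n_initiated`, `n_successful`, `dsr`; per nest: fate and
#'   spans of all nests, discovered or not).
#' @export
simulate_encounter_histories <- function(config, covariates = NULL,
                                         seed = 1, n_nests = NULL) {
  if (is.null(covariates)) covariates <- simulate_covariates(config, seed)
  set.seed(seed + 2L)
  M <- config$M
  lambda <- .sim_lambda(config, covariates)
  dsr_i <- plogis(qlogis(config$dsr) +
                    .std_effects(covariates, config$dsr_beta))
  n_i <- if (is.null(n_nests)) rpois(M, lambda) else {
    base <- rep(n_nests %/% M, M)
    extra <- n_nests %% M
    if (extra) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  P <- config$nest_period_days
  rows <- list(); truth_rows <- list()
  id <- 0L
  for (i in seq_len(M)) {
    ni <- n_i[i]
    if (!ni) next
    for (k in seq_len(ni)) {
      id <- id + 1L
      d0 <- sample.int(config$season_days, 1)
      # days survived before failure; P survived days = success
      alive <- rbinom(P, 1, dsr_i[i])
      A <- if (all(alive == 1)) P else which(alive == 0)[1] - 1L
      success <- A == P
      # active on days d0 .. d0 + A - 1 (A = 0 fails the first day and
      # is never observable)
      search <- d0 + sample.int(P, 1) - 1L
      found <- A > 0 && search <= d0 + A - 1L
      truth_rows[[id]] <- data.frame(plot_id = paste0("plot", i),
                                     active_days = A,
                                     success = success, found = found)
      if (!found) next
      visits <- seq(search, by = config$check_interval_days,
                    length.out = ceiling(P / config$check_interval_days) + 2)
      if (success) {
        la <- max(visits[visits <= d0 + P - 1L])
        lc <- la
      } else {
        fail_day <- d0 + A  # first inactive day
        la <- max(visits[visits < fail_day])
        lc <- min(visits[visits >= fail_day])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        nest_id = paste0("nest", id), plot_id = paste0("plot", i),
        first_found = search, last_active = la, last_checked = lc,
        fate = if (success) "success" else "failure",
        year = if (i <= M / 2) "y1" else "y2",
        stringsAsFactors = FALSE)
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nest_id = character(), plot_id = character(),
               first_found = integer(), last_active = integer(),
               last_checked = integer(), fate = character(),
               year = character())
  if (nrow(rec)) {
    pc <- covariates[match(rec$plot_id, paste0("plot", seq_len(M))), ,
                     drop = FALSE]
    rownames(pc) <- NULL
    rec <- cbind(rec, pc)
    # nest-site covariates: plot value plus local noise
    for (nm in c("biomass", "forb", "litter", "exotic")) {
      noise <- if (nm == "biomass") rnorm(nrow(rec), 0, 150) else
        rnorm(nrow(rec), 0, 0.03)
      rec[[paste0("nest_", nm)]] <- pmax(rec[[nm]] + noise, 0)
    }
  }
  tr <- do.call(rbind, truth_rows)
  per_plot <- data.frame(
    plot_id = paste0("plot", seq_len(M)),
    n_initiated = n_i,
    n_successful = vapply(seq_len(M), function(i) {
      if (is.null(tr)) return(0L)
      sum(tr$success[tr$plot_id == paste0("plot", i)])
    }, integer(1)),
    dsr = dsr_i)
  list(records = if (nrow(rec)) nest_records(rec) else rec,
       truth = list(per_plot = per_plot, per_nest = tr))
}

#' Simulate a complete synthetic study
#'
#' Covariates, replicated counts, and encounter histories from a single
#' seed, with the full truth channel for recovery experiments.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (all randomness flows from it).
#' @return list with `covariates`, `counts` (list of `data`, `truth`),
#'   `encounters` (list of `records`, `truth`), `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  covariates <- simulate_covariates(config, seed)
  counts <- simulate_counts(config, covariates, seed)
  encounters <- simulate_encounter_histories(config, covariates, seed)
  list(covariates = covariates, counts = counts, encounters = encounters,
       config = config, seed = seed)
}

#' Write a synthetic study to delimited text files
#'
#' Emits the counts file, plot-covariate file, nest-record file, the
#' plain encounter-history export, and a truth file, all CSV/text.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "plot_covariates.csv",
                            "nest_records.csv", "encounter_histories.txt",
                            "truth_plots.csv"))
  write_nest_counts(study$counts$data, paths[1], paths[2])
  if (nrow(study$encounters$records)) {
    write_nest_records(study$encounters$records, paths[3])
    write_encounter_histories(study$encounters$records, paths[4])
  }
  tr <- study$encounters$truth$per_plot
  tr$lambda <- study$counts$truth$lambda
  tr$N1 <- study$counts$truth$N[, 1]
  write.csv(tr, paths[5], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
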