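#' @useDynLib opennest, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dbinom dpois dnbinom optim optimHess plogis qlogis
#'   qnorm qt pnorm rnorm rpois rbinom runif rnbinom cor cor.test sd lm
#'   coef vcov confint pt shapiro.test complete.cases setNames residuals
#'   fitted predict
#' @importFrom utils read.csv write.csv head
NULL

# ---- CountDataset ----------------------------------------------------------

#' Construct a replicated nest-count dataset
#'
#' Bundles the plots-by-occasions count matrix with its missing-occasion
#' mask and the survey- and plot-level covariates used by the density
#' model. Counts are nests detected per rope-drag survey; occasions that
#' were never surveyed are flagged in `observed_mask` and excluded from
#' all likelihood products rather than zero-filled.
#'
#' @param y integer matrix, M plots x T occasions of nest counts. `NA` is
#'   allowed only where `observed_mask` is `FALSE`.
#' @param observed_mask logical matrix, same shape as `y`; `TRUE` where the
#'   occasion was actually surveyed. Defaults to `!is.na(y)`.
#' @param plot_ids character vector of plot identifiers (length M).
#' @param survey_covariates named list of M x T numeric matrices of
#'   per-survey conditions (e.g. date, time, wind, temp, cloud). Values may
#'   be `NA` only at unobserved occasions.
#' @param plot_covariates data frame with one row per plot (e.g. biomass
#'   kg/ha, proportional covers, slope in degrees).
#' @return an object of class `nest_counts`.
#' @export
nest_counts <- function(y, observed_mask = NULL, plot_ids = NULL,
                        survey_covariates = list(),
                        plot_covariates = NULL) {
  y <- as.matrix(y)
  M <- nrow(y); T_ <- ncol(y)
  if (is.null(observed_mask)) observed_mask <- !is.na(y)
  observed_mask <- as.matrix(observed_mask)
  if (!identical(dim(observed_mask), dim(y)))
    stop("observed_mask must have the same dimensions as y")
  if (is.null(plot_ids)) plot_ids <- rownames(y)
  if (is.null(plot_ids)) plot_ids <- paste0("plot", seq_len(M))
  if (length(plot_ids) != M) stop("plot_ids length must equal nrow(y)")
  obs <- y[observed_mask]
  if (anyNA(obs)) stop("counts may not be NA at surveyed occasions")
  if (any(obs < 0) || any(obs != round(obs)))
    stop("counts must be non-negative integers at surveyed occasions")
  storage.mode(y) <- "integer"
  for (nm in names(survey_covariates)) {
    cv <- as.matrix(survey_covariates[[nm]])
    if (!identical(dim(cv), dim(y)))
      stop("survey covariate '", nm, "' must be an M x T matrix")
    if (anyNA(cv[observed_mask]))
      stop("survey covariate '", nm, "' is NA at a surveyed occasion")
    survey_covariates[[nm]] <- cv
  }
  if (!is.null(plot_covariates)) {
    plot_covariates <- as.data.frame(plot_covariates)
    if (nrow(plot_covariates) != M)
      stop("plot_covariates must have one row per plot")
  }
  structure(list(y = y, observed_mask = observed_mask, plot_ids = plot_ids,
                 survey_covariates = survey_covariates,
                 plot_covariates = plot_covariates),
            class = "nest_counts")
}

#' @export
print.nest_counts <- function(x, ...) {
  cat("Replicated nest-count dataset:", nrow(x$y), "plots x", ncol(x$y),
      "occasions\n")
  cat("  surveyed occasions:", sum(x$observed_mask), "of",
      length(x$observed_mask), "\n")
  cat("  total nests counted:", sum(x$y[x$observed_mask]), "\n")
  if (length(x$survey_covariates))
    cat("  survey covariates:", paste(names(x$survey_covariates),
                                      collapse = ", "), "\n")
  if (!is.null(x$plot_covariates))
    cat("  plot covariates:", paste(names(x$plot_covariates),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Read a replicated count dataset from delimited text
#'
#' The count file is long format with columns `plot_id`, `occasion`,
#' `count`, plus any per-survey covariate columns; (plot, occasion) pairs
#' absent from the file are treated as unsurveyed. The plot-covariate file
#' is wide, one row per plot with a `plot_id` column.
#'
#' @param counts_path path to the long-format counts CSV.
#' @param plot_cov_path optional path to the wide plot-covariate CSV.
#' @return a [nest_counts] object.
#' @export
read_nest_counts <- function(counts_path, plot_cov_path = NULL) {
  long <- read.csv(counts_path, stringsAsFactors = FALSE)
  need <- c("plot_id", "occasion", "count")
  if (!all(need %in% names(long)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(long[, c("plot_id", "occasion")]))
    stop("duplicate (plot_id, occasion) rows in counts file")
  plots <- unique(long$plot_id)
  T_ <- max(long$occasion)
  if (any(long$occasion < 1)) stop("occasion indices must be >= 1")
  M <- length(plots)
  y <- matrix(NA_integer_, M, T_, dimnames = list(plots, NULL))
  idx <- cbind(match(long$plot_id, plots), long$occasion)
  if (any(long$count < 0, na.rm = TRUE))
    stop("negative counts in counts file")
  y[idx] <- long$count
  cov_cols <- setdiff(names(long), need)
  scov <- lapply(cov_cols, function(nm) {
    m <- matrix(NA_real_, M, T_)
    m[idx] <- long[[nm]]
    m
  })
  names(scov) <- cov_cols
  pcov <- NULL
  if (!is.null(plot_cov_path)) {
    pcov <- read.csv(plot_cov_path, stringsAsFactors = FALSE)
    if (!"plot_id" %in% names(pcov))
      stop("plot covariate file must have a plot_id column")
    if (!setequal(pcov$plot_id, plots))
      stop("plot ids differ between counts and plot covariate files")
    pcov <- pcov[match(plots, pcov$plot_id), , drop = FALSE]
    rownames(pcov) <- NULL
    pcov$plot_id <- NULL
  }
  nest_counts(y, plot_ids = as.character(plots), survey_covariates = scov,
              plot_covariates = pcov)
}

#' Write a count dataset to delimited text
#'
#' Inverse of [read_nest_counts()]: emits the long-format counts file
#' (surveyed occasions only) and, when plot covariates are present, the
#' wide plot-covariate file.
#'
#' @param data a [nest_counts] object.
#' @param counts_path,plot_cov_path output paths.
#' @export
write_nest_counts <- function(data, counts_path, plot_cov_path = NULL) {
  obs <- which(data$observed_mask, arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  long <- data.frame(plot_id = data$plot_ids[obs[, 1]],
                     occasion = obs[, 2],
                     count = data$y[obs])
  for (nm in names(data$survey_covariates))
    long[[nm]] <- data$survey_covariates[[nm]][obs]
  write.csv(long, counts_path, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_cov_path) && !is.null(data$plot_covariates)) {
    wide <- cbind(plot_id = data$plot_ids, data$plot_covariates)
    write.csv(wide, plot_cov_path, row.names = FALSE, quote = FALSE)
  }
  invisible(data)
}

# ---- Encounter records -----------------------------------------------------

#' Construct nest encounter records
#'
#' One row per monitored nest. Days are integers counted from a season
#' origin (day 1 = May 1). A successful nest has `last_active ==
#' last_checked`; a failed nest failed somewhere in the half-open window
#' `(last_active, last_checked]`.
#'
#' @param df data frame with columns `nest_id`, `plot_id`, `first_found`,
#'   `last_active`, `last_checked`, `fate` ("success"/"failure"); optional
#'   `year` and any covariate columns.
#' @return a validated data frame of class `nest_records`.
#' @export
nest_records <- function(df) {
  df <- as.data.frame(df)
  need <- c("nest_id", "plot_id", "first_found", "last_active",
            "last_checked", "fate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$fate %in% c("success", "failure")))
    stop("fate must be 'success' or 'failure'")
  if (any(df$first_found > df$last_active))
    stop("first_found must be <= last_active")
  if (any(df$last_active > df$last_checked))
    stop("last_active must be <= last_checked")
  bad <- df$fate == "success" & df$last_active != df$last_checked
  if (any(bad))
    stop("successful nests must have last_active == last_checked")
  bad <- df$fate == "failure" & df$last_active == df$last_checked
  if (any(bad))
    stop("failed nests need a positive failure window (last_checked > last_active)")
  class(df) <- c("nest_records", "data.frame")
  df
}

#' Read / write nest encounter records
#'
#' CSV with one row per nest. [write_encounter_histories()] additionally
#' exports the plain whitespace-separated encounter-history format
#' `first_found last_active last_checked fate` (fate coded 1 = success,
#' 0 = failure), one line per nest.
#'
#' @param path file path.
#' @return [read_nest_records()] returns a `nest_records` data frame.
#' @export
read_nest_records <- function(path) {
  nest_records(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_nest_records
#' @param records a `nest_records` data frame.
#' @export
write_nest_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' @rdname read_nest_records
#' @export
write_encounter_histories <- function(records, path) {
  lines <- paste(records$first_found, records$last_active,
                 records$last_checked,
                 ifelse(records$fate == "success", 1L, 0L))
  writeLines(lines, path)
  invisible(records)
}

# ---- Vegetation: cover bins and biomass calibration ------------------------

# Legal ocular cover bins (percent) and their midpoints as proportions.
.cover_bins <- c("0-5" = 0.025, "6-25" = 0.155, "26-50" = 0.38,
                 "51-75" = 0.63, "76-95" = 0.855, "96-100" = 0.98)

#' Midpoint of an ocular cover bin
#'
#' Cover is recorded in six ordinal percentage bins (0-5, 6-25, 26-50,
#' 51-75, 76-95, 96-100); models use the bin midpoint as a continuous
#' proportion, the standard Daubenmire-frame convention.
#'
#' @param bin_label character vector of bin labels; an en dash is accepted
#'   in place of the hyphen.
#' @return numeric vector of midpoints in `[0, 1]`.
#' @export
#' @examples
#' cover_bin_midpoint("0-5")     # 0.025
#' cover_bin_midpoint("96-100")  # 0.98
cover_bin_midpoint <- function(bin_label) {
  key <- gsub("–", "-", as.character(bin_label))
  out <- unname(.cover_bins[key])
  if (anyNA(out))
    stop("unknown cover bin: ",
         paste(unique(key[is.na(out)]), collapse = ", "),
         " (legal bins: ", paste(names(.cover_bins), collapse = ", "), ")")
  out
}

#' Calibrate ocular biomass estimates against clip plots
#'
#' Visual green-biomass estimates (g per 20 x 50 cm frame) are corrected
#' in two additive steps: each observer's estimates are shifted by that
#' observer's mean (estimated - clipped) green-weight difference, then
#' converted to dry mass by subtracting the overall mean (green - dry)
#' difference from the drying subsample. Dry masses are floored at zero,
#' and the 0.1 m2 frame area scales g/frame to kg/ha (x 100).
#'
#' @param estimates numeric vector of estimated green mass, g per frame.
#' @param observer_id character vector, same length, naming the observer
#'   of each estimate.
#' @param green_calib data frame with columns `observer_id`,
#'   `estimated_green`, `clipped_green` (g).
#' @param dry_calib data frame with columns `clipped_green`, `dry` (g).
#' @return data frame with corrected `green_g`, `dry_g` (per frame) and
#'   `dry_kg_ha`.
#' @export
calibrate_biomass <- function(estimates, observer_id, green_calib,
                              dry_calib) {
  stopifnot(length(estimates) == length(observer_id))
  if (any(estimates < 0)) stop("estimated masses must be >= 0")
  off <- tapply(green_calib$estimated_green - green_calib$clipped_green,
                green_calib$observer_id, mean)
  unknown <- setdiff(unique(observer_id), names(off))
  if (length(unknown))
    stop("observer(s) absent from calibration set: ",
         paste(unknown, collapse = ", "))
  green <- pmax(estimates - unname(off[observer_id]), 0)
  dry_offset <- mean(dry_calib$clipped_green - dry_calib$dry)
  dry <- pmax(green - dry_offset, 0)
  # 20 x 50 cm frame = 0.1 m2; g / 0.1 m2 = 10 g/m2 = 100 kg/ha
  data.frame(green_g = green, dry_g = dry, dry_kg_ha = dry * 100)
}

# ---- Covariate standardization --------------------------------------------

#' Standardize covariate columns to mean zero, unit SD
#'
#' All covariates entering the density, detection, and survival models are
#' centred and scaled (sample SD, n - 1 denominator) to aid convergence;
#' the centring parameters are retained so coefficients can be reported
#' back on the real scale.
#'
#' @param x data frame or matrix of numeric covariates.
#' @return list with `data` (standardized data frame), `center` and
#'   `scale` (named numeric vectors).
#' @export
standardize_covariates <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num)) stop("all covariate columns must be numeric")
  ctr <- vapply(x, mean, numeric(1), na.rm = TRUE)
  scl <- vapply(x, sd, numeric(1), na.rm = TRUE)
  if (any(!is.finite(scl)) || any(scl == 0))
    stop("constant covariate column(s): ",
         paste(names(x)[!is.finite(scl) | scl == 0], collapse = ", "))
  out <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                              x, ctr, scl, SIMPLIFY = FALSE))
  list(data = out, center = ctr, scale = scl)
}

#' Undo a standardization
#'
#' @param std the list returned by [standardize_covariates()].
#' @param data optional standardized data frame to map back; defaults to
#'   `std$data`.
#' @return data frame on the original scale.
#' @export
unstandardize_covariates <- function(std, data = std$data) {
  as.data.frame(mapply(function(col, m, s) col * s + m,
                       as.data.frame(data), std$center, std$scale,
                       SIMPLIFY = FALSE))
}

#' Map a standardized-scale slope to the real scale
#'
#' A coefficient estimated on a covariate scaled by `s` corresponds to
#' `beta / s` per original unit (quadratic terms scale by `s^2`).
#'
#' @param beta coefficient on the standardized scale.
#' @param scale the covariate's SD used in standardization.
#' @param degree polynomial degree of the term (1 = linear, 2 = quadratic).
#' @return coefficient per original covariate unit.
#' @export
real_scale_coef <- function(beta, scale, degree = 1) beta / scale^degree
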