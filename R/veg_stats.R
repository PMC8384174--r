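# Vegetation-sampling support: the sample-size formula with its
# small-sample correction, pairwise collinearity screening with field
# retention preferences, and the nest-site vs plot-scale correlation
# analysis.

#' Required number of vegetation sampling points
#'
#' Uncorrected sample size `n = z^2 s^2 / B^2` with `B = mean x
#' precision`, then corrected for small samples by iterating the same
#' formula with the t quantile at the current sample size's degrees of
#' freedom until the integer ceiling stabilizes.
#'
#' @param mean,sd pilot sample mean (> 0) and SD of the measurement.
#' @param precision target half-width as a fraction of the mean
#'   (default 0.15).
#' @param conf confidence level for the interval (default 0.90, giving
#'   z = 1.64).
#' @return integer corrected sample size (at least 1).
#' @export
required_sample_size <- function(mean, sd, precision = 0.15, conf = 0.90) {
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(1L)
  z <- round(qnorm(1 - (1 - conf) / 2), 2)  # 1.64 at 90%
  B <- mean * precision
  n <- max(ceiling(z^2 * sd^2 / B^2), 2L)
  # small-sample correction: replace z by t_{df = n - 1} and iterate
  for (it in 1:100) {
    tq <- qt(1 - (1 - conf) / 2, df = n - 1)
    n2 <- max(ceiling(tq^2 * sd^2 / B^2), 2L)
    if (n2 == n) break
    n <- n2
  }
  as.integer(n)
}

#' Pairwise collinearity screen with retention priorities
#'
#' Computes the pairwise Pearson correlation matrix and, for every pair
#' with `|r| >=` the threshold, removes the lower-priority member. The
#' shipped default priorities reflect field practice for grassland
#' vegetation: herbaceous biomass is retained over VOR and grass heights,
#' shrub cover over shrub height, litter cover over bare ground; biomass
#' and exotic-grass cover are declared mutually exclusive (each retained,
#' never modeled together) rather than one removed.
#'
#' @param covariates data frame of numeric covariates.
#' @param threshold correlation magnitude at or above which a pair is
#'   treated as collinear (default 0.6).
#' @param priority character vector, highest priority first; every member
#'   of a collinear pair must appear in it.
#' @param mutually_exclusive list of length-2 character vectors naming
#'   pairs to keep but never co-model.
#' @return object of class `collinearity_screen`: `correlation` matrix,
#'   `retained`, `removed` (data frame with `covariate`, `partner`, `r`),
#'   `mutually_exclusive`.
#' @export
collinearity_screen <- function(covariates, threshold = 0.6,
                                priority = default_veg_priority(),
                                mutually_exclusive =
                                  list(c("biomass", "exotic"))) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least two covariates")
  cm <- cor(covariates, use = "pairwise.complete.obs")
  nm <- colnames(cm)
  excl_key <- vapply(mutually_exclusive, function(p)
    paste(sort(p), collapse = "|"), character(1))
  removed <- data.frame(covariate = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  retained <- nm
  excl_found <- list()
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))  # strongest correlations first
    for (k in ord) {
      a <- nm[pairs[k, 1]]; b <- nm[pairs[k, 2]]
      if (!(a %in% retained) || !(b %in% retained)) next
      if (paste(sort(c(a, b)), collapse = "|") %in% excl_key) {
        excl_found[[length(excl_found) + 1]] <- c(a, b)
        next
      }
      pa <- match(a, priority); pb <- match(b, priority)
      if (is.na(pa) || is.na(pb))
        stop("priority list is missing a member of the correlated pair ",
             a, " / ", b)
      drop <- if (pa <= pb) b else a
      keep <- if (pa <= pb) a else b
      retained <- setdiff(retained, drop)
      removed <- rbind(removed,
                       data.frame(covariate = drop, partner = keep,
                                  r = cm[a, b]))
    }
  }
  structure(list(correlation = cm, retained = retained, removed = removed,
                 mutually_exclusive = excl_found, threshold = threshold),
            class = "collinearity_screen")
}

#' Default retention priorities for grassland vegetation covariates
#'
#' Highest priority first. Management-relevant structural measures are
#' preferred over their proxies.
#'
#' @return character vector of covariate names.
#' @export
default_veg_priority <- function() {
  c("biomass", "exotic", "shrub", "litter", "forb", "residual_grass",
    "slope", "biomass_sd", "litter_depth", "vor", "grass_height",
    "residual_height", "shrub_height", "bare_ground")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("Collinearity screen (|r| >=", x$threshold, ")\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$removed)) {
    cat("  removed:\n")
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("    %s (r = %.2f with %s)\n", x$removed$covariate[i],
                  x$removed$r[i], x$removed$partner[i]))
  }
  for (p in x$mutually_exclusive)
    cat("  mutually exclusive (never co-modeled):",
        paste(p, collapse = " / "), "\n")
  invisible(x)
}

#' Nest-site vs plot-scale correlation analysis
#'
#' For plots containing at least one nest, correlates the nest-site value
#' of each vegetation measure with the plot average, after an optional
#' variance-stabilizing transform. An association is deemed meaningful
#' when `|r| > 0.6` and `P < 0.05`.
#'
#' @param nest_values,plot_values data frames (paired rows, one per plot
#'   with a nest) with matching covariate columns.
#' @param transforms named character vector mapping covariate name to
#'   `"log"`, `"logit"` or `"none"`; unnamed covariates default to
#'   `"none"`. Proportions of exactly 0 or 1 are nudged by `1/(2n)`
#'   before the logit.
#' @param r_threshold,p_threshold meaningfulness cutoffs.
#' @return data frame with one row per covariate: `r`, `p`, `meaningful`.
#' @export
cross_scale_correlation <- function(nest_values, plot_values,
                                    transforms = character(),
                                    r_threshold = 0.6,
                                    p_threshold = 0.05) {
  nest_values <- as.data.frame(nest_values)
  plot_values <- as.data.frame(plot_values)
  common <- intersect(names(nest_values), names(plot_values))
  if (!length(common)) stop("no common covariate columns")
  if (nrow(nest_values) != nrow(plot_values))
    stop("nest and plot tables must be paired by plot")
  if (nrow(nest_values) < 3) stop("need at least 3 paired plots")
  tr <- function(v, how) {
    n <- length(v)
    switch(how,
           log = log(v),
           logit = { v <- pmin(pmax(v, 1 / (2 * n)), 1 - 1 / (2 * n))
                     qlogis(v) },
           v)
  }
  out <- lapply(common, function(nm) {
    how <- if (nm %in% names(transforms)) transforms[[nm]] else "none"
    x <- tr(nest_values[[nm]], how)
    y <- tr(plot_values[[nm]], how)
    ok <- complete.cases(x, y)
    ct <- cor.test(x[ok], y[ok])
    data.frame(covariate = nm, transform = how,
               r = unname(ct$estimate), p = ct$p.value,
               meaningful = abs(ct$estimate) > r_threshold &
                 ct$p.value < p_threshold)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
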