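test_that("sample-size formula matches the hand arithmetic", {
  # sd equal to the mean: uncorrected n = 1.64^2 / 0.15^2 = 119.5,
  # large enough that the t correction barely moves it
  n <- required_sample_size(10, 10)
  expect_gte(n, 120)
  expect_lte(n, 125)
  # uncorrected 2.6896 * 400 / 225 = 4.78; iterated t correction raises it
  n2 <- required_sample_size(100, 20)
  expect_gte(n2, 5)
  expect_lte(n2, 10)
  expect_equal(required_sample_size(10, 0), 1L)
  expect_error(required_sample_size(0, 5), "positive")
})

test_that("sample size is monotone in sd, mean, and precision", {
  sds <- c(5, 10, 20, 40)
  ns <- vapply(sds, function(s) required_sample_size(100, s), integer(1))
  expect_true(all(diff(ns) >= 0))
  means <- c(50, 100, 200)
  nm <- vapply(means, function(m) required_sample_size(m, 30), integer(1))
  expect_true(all(diff(nm) <= 0))
  precs <- c(0.05, 0.1, 0.2)
  np <- vapply(precs, function(p)
    required_sample_size(100, 30, precision = p), integer(1))
  expect_true(all(diff(np) <= 0))
})

# Construct covariates with controlled correlations by mixing a shared
# latent component.
make_correlated <- function(n, target, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  function(r) r * z + sqrt(1 - r^2) * rnorm(n)
}

test_that("collinearity screen removes the lower-priority partner", {
  gen <- make_correlated(400, seed = 61)
  biomass <- gen(1)
  df <- data.frame(biomass = biomass,
                   vor = 0.93 * biomass + sqrt(1 - 0.93^2) * rnorm(400),
                   forb = gen(0.2),
                   exotic = 0.77 * biomass + sqrt(1 - 0.77^2) * rnorm(400))
  sc <- collinearity_screen(df)
  expect_true("vor" %in% sc$removed$covariate)
  expect_false("vor" %in% sc$retained)
  expect_true(all(c("biomass", "forb", "exotic") %in% sc$retained))
  # biomass-exotic flagged mutually exclusive, not removed
  expect_length(sc$mutually_exclusive, 1)
  expect_setequal(sc$mutually_exclusive[[1]], c("biomass", "exotic"))
})

test_that("sub-threshold pairs are retained and screening is idempotent", {
  set.seed(67)
  z <- rnorm(500)
  df <- data.frame(biomass = z,
                   forb = 0.55 * z + sqrt(1 - 0.55^2) * rnorm(500))
  sc <- collinearity_screen(df)
  expect_setequal(sc$retained, c("biomass", "forb"))
  expect_equal(nrow(sc$removed), 0)

  # rescreening an already-screened set removes nothing
  gen <- make_correlated(400, seed = 61)
  biomass <- gen(1)
  df2 <- data.frame(biomass = biomass,
                    vor = 0.93 * biomass + sqrt(1 - 0.93^2) * rnorm(400),
                    forb = gen(0.2))
  sc2 <- collinearity_screen(df2)
  sc3 <- collinearity_screen(df2[sc2$retained])
  expect_equal(nrow(sc3$removed), 0)
  expect_setequal(sc3$retained, sc2$retained)
})

test_that("screen demands a priority entry for correlated members", {
  set.seed(71)
  z <- rnorm(200)
  df <- data.frame(mystery1 = z, mystery2 = 0.9 * z + 0.3 * rnorm(200))
  expect_error(collinearity_screen(df), "priority")
  sc <- collinearity_screen(df, priority = c("mystery1", "mystery2"))
  expect_equal(sc$retained, "mystery1")
})

test_that("cross-scale correlation flags identical series as meaningful", {
  set.seed(73)
  v <- runif(20, 0.1, 0.9)
  out <- cross_scale_correlation(data.frame(forb = v),
                                 data.frame(forb = v))
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_true(out$meaningful)
  expect_error(cross_scale_correlation(data.frame(a = 1:2),
                                       data.frame(a = 1:2)), "3")
})

test_that("cross-scale false positives are rare and power is adequate", {
  set.seed(79)
  fp <- vapply(1:60, function(i) {
    out <- cross_scale_correlation(data.frame(x = rnorm(71)),
                                   data.frame(x = rnorm(71)))
    out$meaningful
  }, logical(1))
  expect_lte(mean(fp), 0.10)

  hits <- vapply(1:60, function(i) {
    z <- rnorm(71)
    nest <- 0.8 * z + sqrt(1 - 0.64) * rnorm(71)
    out <- cross_scale_correlation(data.frame(x = nest),
                                   data.frame(x = z))
    out$meaningful
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("transforms are applied and respect proportion bounds", {
  set.seed(83)
  v <- c(0, runif(18), 1)  # includes exact 0 and 1
  out <- cross_scale_correlation(data.frame(cov = v),
                                 data.frame(cov = v),
                                 transforms = c(cov = "logit"))
  expect_true(is.finite(out$r))
  expect_equal(out$transform, "logit")
  # Pearson r is invariant to affine maps, so the log transform changes
  # r only through nonlinearity, not scale
  w <- exp(rnorm(30))
  r1 <- cross_scale_correlation(data.frame(b = w), data.frame(b = 3 * w),
                                transforms = c(b = "log"))
  expect_equal(r1$r, 1, tolerance = 1e-12)
})
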