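test_that("initial pmf matches the closed-form mixtures", {
  pmf <- initial_pmf(1, K = 10, mixture = "poisson")
  expect_equal(pmf[1], exp(-1))
  expect_equal(pmf, exp(-1) / factorial(0:10), tolerance = 1e-12)

  # degenerate limit: all mass at zero
  expect_equal(initial_pmf(0, K = 5)[1], 1)

  # negative binomial checked against the textbook pmf written out from
  # the gamma-function form, not stats::dnbinom
  alpha <- 2.16; mu <- 2; K <- 50
  n <- 0:K
  ref <- exp(lgamma(n + alpha) - lgamma(alpha) - lfactorial(n)) *
    (alpha / (alpha + mu))^alpha * (mu / (alpha + mu))^n
  expect_equal(initial_pmf(mu, K, "negbin", alpha), ref,
               tolerance = 1e-12)

  expect_error(initial_pmf(1, K = 10, mixture = "negbin"), "alpha")
  expect_error(initial_pmf(1, K = -1), "K")
})

test_that("transition pmf has the right limits and simulation law", {
  # closure limit: identity row
  expect_equal(transition_pmf(3, gamma = 0, omega = 1, K = 8),
               c(0, 0, 0, 1, rep(0, 5)))
  # no survivors possible from zero: pure Poisson recruits
  expect_equal(transition_pmf(0, gamma = 0.5, omega = 0.3, K = 10),
               dpois(0:10, 0.5), tolerance = 1e-12)

  # Monte-Carlo oracle: binomial survivors + Poisson recruits
  set.seed(31)
  m <- 3; omega <- 0.87; gamma <- 0.2; K <- 15; nsim <- 2e5
  draws <- rbinom(nsim, m, omega) + rpois(nsim, gamma)
  pmf <- transition_pmf(m, gamma, omega, K)
  for (n in 0:6) {
    phat <- mean(draws == n)
    se <- sqrt(pmf[n + 1] * (1 - pmf[n + 1]) / nsim)
    expect_lt(abs(phat - pmf[n + 1]), 3 * se + 1e-12)
  }
  # rows sum to one minus truncation mass, which is tiny at ample K
  expect_equal(sum(pmf), 1, tolerance = 1e-8)
})

test_that("site likelihood collapses correctly in degenerate designs", {
  # perfect detection, single occasion: just the mixture pmf
  ll <- dm_site_loglik(matrix(3L, 1, 1), matrix(TRUE, 1, 1), lambda = 2,
                       p = matrix(1, 1, 1), gamma = 0, omega = 1, K = 20)
  expect_equal(ll, dpois(3, 2, log = TRUE), tolerance = 1e-12)

  # closure with perfect detection cannot produce growing counts
  ll2 <- dm_site_loglik(matrix(c(2L, 3L), 1, 2), matrix(TRUE, 1, 2),
                        lambda = 2, p = matrix(1, 1, 2), gamma = 0,
                        omega = 1, K = 20)
  expect_identical(ll2, -Inf)

  # K below the maximum count is a usage error
  expect_error(dm_site_loglik(matrix(5L, 1, 1), matrix(TRUE, 1, 1), 2,
                              matrix(0.5, 1, 1), 0, 1, K = 3),
               "maximum observed count")
})

test_that("forward recursion equals trajectory enumeration", {
  set.seed(71)
  for (rep in 1:25) {
    K <- sample(5:12, 1); Tn <- sample(1:3, 1)
    lambda <- runif(1, 0.2, 4); gamma <- runif(1, 0, 1.5)
    omega <- runif(1); p <- runif(Tn, 0.05, 0.95)
    y <- vapply(seq_len(Tn), function(t) sample(0:4, 1), integer(1))
    mask <- runif(Tn) > 0.2; if (!any(mask)) mask[1] <- TRUE
    mix <- sample(c("poisson", "negbin"), 1)
    al <- if (mix == "negbin") runif(1, 0.5, 4) else NULL
    a <- dm_site_loglik(matrix(y, 1), matrix(mask, 1), lambda,
                        matrix(p, 1), gamma, omega, K, mix, al)
    b <- enum_site_loglik(y, mask, lambda, p, gamma, omega, K, mix, al)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("site likelihood is stable in K once ample", {
  set.seed(5)
  y <- matrix(rpois(6, 1), 2, 3)
  mask <- matrix(TRUE, 2, 3)
  base <- sum(dm_site_loglik(y, mask, rep(2.5, 2), matrix(0.3, 2, 3),
                             0.1, 0.85, K = 60))
  dbl <- sum(dm_site_loglik(y, mask, rep(2.5, 2), matrix(0.3, 2, 3),
                            0.1, 0.85, K = 120))
  expect_lt(abs(dbl - base), 1e-6)
})

test_that("fitting recovers truth under perfect closed-population detection", {
  set.seed(21)
  M <- 200
  N <- rpois(M, 3)
  d <- nest_counts(matrix(rep(N, 2), M, 2))
  f <- fit_dm(d, K = max(N) + 30, n_starts = 1)
  # with p = 1, omega = 1, gamma = 0 the generating process is closed;
  # lambda collapses to the Poisson MLE = mean count
  expect_equal(unname(exp(f$estimates[1])), mean(N), tolerance = 0.05)
  expect_gt(f$parameters$omega, 0.99)
  expect_gt(mean(f$p_hat), 0.95)
})

test_that("all-zero counts drive lambda to the boundary with a flag", {
  d <- nest_counts(matrix(0L, 20, 2))
  f <- fit_dm(d, K = 30, n_starts = 1)
  expect_lt(exp(f$estimates[1]), 0.01)
  expect_true(f$boundary)
})

test_that("K-stability check reports rather than throws", {
  set.seed(9)
  sim <- simulate_counts(sim_config(M = 40), seed = 4)
  f <- fit_dm(sim$data, K = max(sim$data$y, na.rm = TRUE) + 30,
              n_starts = 1)
  rep_ <- check_K_stability(f, increments = 15L)
  expect_type(rep_$stable, "logical")
  expect_true(is.finite(rep_$max_delta))
  expect_error(check_K_stability(f, increments = -5), "positive")
})

test_that("closure percent change follows (1 + gamma - omega) x 100", {
  ct <- closure_test(gamma = 0.00002, omega = 0.87)
  expect_equal(ct$percent_change_per_interval, -12.998)  # 13% decrease
  expect_equal(closure_test(gamma = 0, omega = 1)$percent_change_per_interval, 0)
  expect_equal(closure_test(gamma = 0.3, omega = 1)$percent_change_per_interval, 30)
  # closure decision from Wald intervals
  ct2 <- closure_test(gamma = 0.00002, omega = 0.87, se_gamma = 0.002,
                      se_omega = 0.04)
  expect_false(ct2$closed)   # omega interval excludes 1
  ct3 <- closure_test(gamma = 0, omega = 1, se_gamma = 0.01,
                      se_omega = 0.01)
  expect_true(ct3$closed)
})

test_that("latent posterior is exact against brute-force Bayes", {
  # perfect detection: posterior degenerate at the observed counts
  y <- matrix(c(2L, 1L), 1, 2)
  d <- nest_counts(y)
  f <- fit_dm(d, K = 10, n_starts = 1,
              start = c(log(2), qlogis(0.999), log(0.01), qlogis(0.5)))
  # evaluate the posterior machinery at fixed, known parameters rather
  # than the fitted ones
  f$lambda_hat <- 2; f$p_hat <- matrix(0.999, 1, 2)
  f$parameters$gamma <- 0.3; f$parameters$omega <- 0.6
  f$parameters$K <- 8
  post <- latent_posterior(f)
  expect_equal(post$mode[1], 2L)

  ref <- enum_posterior(c(2L, 1L), c(TRUE, TRUE), 2,
                        c(0.999, 0.999), 0.3, 0.6, 8)
  expect_equal(unname(post$posterior[[1]]), unname(ref),
               tolerance = 1e-10)

  # imperfect detection, partially observed
  f$p_hat <- matrix(0.4, 1, 2)
  f$data$observed_mask <- matrix(c(TRUE, FALSE), 1, 2)
  post2 <- latent_posterior(f)
  ref2 <- enum_posterior(c(2L, 0L), c(TRUE, FALSE), 2, c(0.4, 0.4),
                         0.3, 0.6, 8)
  expect_equal(unname(post2$posterior[[1]]), unname(ref2),
               tolerance = 1e-10)
  expect_equal(post2$mean[1], sum(0:8 * ref2[, 1]), tolerance = 1e-10)
})

test_that("posterior mode ties break toward the smaller abundance", {
  # engineered exact tie: Poisson(1) puts equal mass on {0, 1}, and an
  # uninformative occasion (p = 0, y = 0) leaves the prior untouched
  d <- nest_counts(matrix(0L, 1, 1))
  f <- fit_dm(d, K = 1, n_starts = 1)
  f$lambda_hat <- 1; f$p_hat <- matrix(0, 1, 1)
  f$parameters$K <- 1
  post <- latent_posterior(f)
  expect_equal(unname(post$posterior[[1]][, 1]), c(0.5, 0.5))
  expect_equal(post$mode[1], 0L)
})

test_that("density predictions honor the log link and the delta method", {
  set.seed(13)
  sim <- simulate_counts(sim_config(M = 60), seed = 8)
  f <- fit_dm(sim$data, n_starts = 1)
  pr <- predict_density(f)
  expect_equal(pr$lambda[1], unname(exp(f$estimates[1])))
  expect_true(all(pr$lower <= pr$lambda & pr$lambda <= pr$upper))
  # c-hat inflation widens intervals
  pr2 <- predict_density(f, c_hat = 2)
  expect_true(all(pr2$upper >= pr$upper))
})

test_that("quadratic vertices match the fitted-coefficient arithmetic", {
  # percent-scale coefficients for forb cover and slope
  expect_equal(quadratic_vertex(0.49, -0.021), 11.6667, tolerance = 1e-4)
  expect_equal(quadratic_vertex(0.34, -0.07), 2.4286, tolerance = 1e-4)
  expect_error(quadratic_vertex(1, 0), "zero")
})
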