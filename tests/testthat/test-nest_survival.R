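test_that("dsr is the inverse-logit of the linear predictor", {
  expect_equal(dsr(c(1, 0), c(0, 0.5)), 0.5)
  b <- c(qlogis(0.93), 0)
  expect_equal(dsr(c(1, 0), b), 0.93)
  # monotone in a positive-coefficient covariate
  xs <- seq(-2, 2, by = 0.5)
  vals <- dsr(cbind(1, xs), c(0.5, 0.7))
  expect_true(all(diff(vals) > 0))
})

test_that("exposure likelihood has the stated closed form", {
  # success found day 5, active through day 15: ten survived days
  s <- 0.9
  ll <- nest_loglik(s, 5, 15, 15, "success")
  expect_equal(ll, 10 * log(s), tolerance = 1e-12)

  # a failure's window term equals enumeration over the failure day
  for (w in 1:10) {
    ll_f <- nest_loglik(s, 1, 1, 1 + w, "failure")
    expect_equal(ll_f, log(enum_failure_prob(s, w)), tolerance = 1e-12)
  }

  # impossible event: certain survival but a recorded failure
  expect_identical(nest_loglik(1, 1, 4, 7, "failure"), -Inf)
  expect_error(nest_loglik(0.9, 1, 5, 5, "failure"), "last_checked")
})

test_that("constant-model MLE solves the Mayfield score equation", {
  # failure days known exactly (1-day windows): the score equation has
  # the closed-form solution s = survived / (survived + failures)
  set.seed(17)
  n <- 120; s_true <- 0.92
  rec <- lapply(seq_len(n), function(i) {
    days <- rgeom(1, 1 - s_true)  # days survived before failure
    if (days >= 20) data.frame(first_found = 1, last_active = 21,
                               last_checked = 21, fate = "success")
    else data.frame(first_found = 1, last_active = 1 + days,
                    last_checked = 2 + days, fate = "failure")
  })
  rec <- do.call(rbind, rec)
  rec$nest_id <- paste0("n", seq_len(n)); rec$plot_id <- "A"
  rec <- nest_records(rec)
  f <- fit_dsr(rec)
  surv_days <- sum(rec$last_active - rec$first_found)
  fails <- sum(rec$fate == "failure")
  expect_equal(unname(f$dsr_null), surv_days / (surv_days + fails),
               tolerance = 1e-6)
})

test_that("all-success data pushes survival to the boundary with a flag", {
  rec <- nest_records(data.frame(
    nest_id = paste0("n", 1:10), plot_id = "A", first_found = 1,
    last_active = 25, last_checked = 25, fate = "success"))
  f <- fit_dsr(rec)
  expect_gt(f$dsr_null, 0.999)
  expect_true(f$boundary)
})

test_that("covariate effects are recovered and null effects covered", {
  set.seed(23)
  cfg <- sim_config(M = 60, dsr_beta = c(biomass = -0.4))
  sim <- simulate_encounter_histories(cfg, seed = 3, n_nests = 600)
  rec <- sim$records
  rec$biomass <- as.numeric(scale(rec$biomass))
  f <- fit_dsr(rec, "biomass")
  expect_lt(f$beta[["biomass"]] , 0)
  expect_lt(abs(f$beta[["biomass"]] + 0.4), 3 * f$se[["biomass"]])
})

test_that("period survival uses the power law and the delta method", {
  ps <- period_survival(0.93, se = 0, T = 30)
  expect_equal(ps$estimate, 0.93^30, tolerance = 1e-12)
  expect_equal(ps$se, 0)
  expect_equal(round(ps$estimate, 4), 0.1134)

  # delta-method SE against Monte-Carlo propagation; the first-order
  # approximation carries a ~7% curvature error for s^30 at this SE, so
  # agreement is asserted to 10%
  set.seed(5)
  s <- 0.93; se_s <- 0.01
  draws <- rnorm(1e5, s, se_s)^30
  ps2 <- period_survival(s, se_s, 30)
  expect_lt(abs(ps2$se - sd(draws)) / sd(draws), 0.10)
})

test_that("apparent success is the fledged fraction", {
  expect_equal(apparent_success(n_success = 76, n_total = 263),
               76 / 263)
  expect_equal(apparent_success(toy_records()), 0.5)
})

test_that("tiered evaluation always includes null and year models", {
  set.seed(29)
  cfg <- sim_config(M = 40)
  sim <- simulate_encounter_histories(cfg, seed = 9, n_nests = 300)
  rec <- sim$records
  for (nm in c("biomass", "forb")) rec[[nm]] <- as.numeric(scale(rec[[nm]]))
  tiers <- tiered_evaluation(rec, nest_terms = list(),
                             plot_terms = list("biomass", "forb"))
  expect_setequal(tiers$nest$table$model, c("null", "year"))
  expect_true(all(c("null", "year", "biomass", "forb") %in%
                    tiers$plot$table$model))
  # weights form a proper distribution and the top model has delta 0
  expect_equal(sum(tiers$plot$table$weight), 1, tolerance = 1e-10)
  expect_equal(tiers$plot$table$delta[1], 0)
})

test_that("supported plot-scale terms propagate to the multi-scale tier", {
  set.seed(37)
  cfg <- sim_config(M = 80, dsr_beta = c(biomass = -0.8))
  sim <- simulate_encounter_histories(cfg, seed = 11, n_nests = 900)
  rec <- sim$records
  rec$biomass <- as.numeric(scale(rec$biomass))
  rec$nest_forb <- as.numeric(scale(rec$nest_forb))
  tiers <- tiered_evaluation(rec, nest_terms = list("nest_forb"),
                             plot_terms = list("biomass"))
  expect_true(any(grepl("biomass", tiers$multi$table$model)))
})
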