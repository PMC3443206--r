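test_that("propensity model recovers saturated closed forms", {
  # intercept-only: everyone gets the marginal response rate
  df <- tibble::tibble(responded = rep(c(TRUE, FALSE), c(75, 25)))
  p <- fit_response_propensity(df, character(0))
  expect_equal(as.numeric(p), rep(0.75, 100), tolerance = 1e-8)

  # balanced binary predictor with group rates 0.6 / 0.9: fitted values
  # equal the group MLEs of the saturated logistic on the 2x2 table
  df2 <- tibble::tibble(
    g = rep(c("a", "b"), each = 100),
    responded = c(rep(c(TRUE, FALSE), c(60, 40)),
                  rep(c(TRUE, FALSE), c(90, 10))))
  p2 <- as.numeric(fit_response_propensity(df2, "g"))
  expect_equal(p2[df2$g == "a"], rep(0.6, 100), tolerance = 1e-8)
  expect_equal(p2[df2$g == "b"], rep(0.9, 100), tolerance = 1e-8)

  # zero non-respondents: propensity 1 everywhere
  df3 <- tibble::tibble(responded = rep(TRUE, 50), x = rnorm(50))
  expect_equal(as.numeric(fit_response_propensity(df3, "x")), rep(1, 50))
})

test_that("propensity errors name degenerate predictors", {
  df <- tibble::tibble(responded = rep(c(TRUE, FALSE), 25),
                       sep = as.numeric(rep(c(TRUE, FALSE), 25)))
  expect_error(fit_response_propensity(df, "sep"), "sep")
  expect_error(fit_response_propensity(df, "nope"), "nope")
})

test_that("non-response adjustment is inverse-propensity arithmetic", {
  expect_equal(nonresponse_adjust(10, 0.5), 20)
  expect_equal(nonresponse_adjust(c(3, 7), c(1, 1)), c(3, 7))
  expect_error(nonresponse_adjust(1, 1.2), "propensity")
  # floor caps weight inflation
  expect_equal(nonresponse_adjust(1, 0.001, floor = 0.02), 50)
})

test_that("weighting chain removes MAR non-response bias", {
  spec <- make_test_spec(n = 3000, k = 1, prevalence = 0.3, beta = 2,
                         severity_fraction = c(0.3, 0.5, 0.8, 1.0), seed = 51)
  spec$nonresponse$coef <- c(severity = -0.6, age_dec = 0, living_alone = 0)
  reps <- 200
  est_w <- est_u <- truth <- numeric(reps)
  for (i in seq_len(reps)) {
    spec$seed <- 5000 + i
    sv <- quiet_survey(spec)
    resp <- build_weights(sv$sample)
    truth[i] <- mean(sv$population$cond_c1)
    est_w[i] <- sum(resp$calibrated_weight * resp$cond_c1) /
      sum(resp$calibrated_weight)
    est_u[i] <- mean(resp$cond_c1)
  }
  bias_w <- mean(est_w - truth)
  bias_u <- mean(est_u - truth)
  se_w <- sd(est_w - truth) / sqrt(reps)
  se_u <- sd(est_u - truth) / sqrt(reps)
  expect_lt(abs(bias_w), 3 * se_w)
  expect_gt(abs(bias_u), 3 * se_u)
})

test_that("raking at a fixed point leaves weights unchanged", {
  df <- tibble::tibble(a = c("x", "x", "y", "y"), w = c(1, 2, 3, 4))
  margins <- tibble::tibble(variable = "a", category = c("x", "y"),
                            target_total = c(3, 7))
  cal <- calibrate_weights(df$w, df, margins)
  expect_equal(cal$weights, df$w)
  expect_equal(cal$iterations, 0L)
})

test_that("single-margin raking is the closed-form ratio adjustment", {
  set.seed(61)
  df <- tibble::tibble(a = sample(c("x", "y", "z"), 60, replace = TRUE),
                       w = runif(60, 0.5, 2))
  margins <- tibble::tibble(variable = "a", category = c("x", "y", "z"),
                            target_total = c(30, 50, 20))
  cal <- calibrate_weights(df$w, df, margins)
  target <- setNames(margins$target_total, margins$category)
  ratio <- target / tapply(df$w, df$a, sum)[names(target)]
  expect_equal(cal$weights, as.numeric(df$w * ratio[df$a]),
               tolerance = 1e-10)
})

test_that("two-margin raking matches margins and preserves odds ratios", {
  df <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"))
  w0 <- c(10, 20, 30, 60)
  margins <- dplyr::bind_rows(
    tibble::tibble(variable = "a", category = c("a1", "a2"),
                   target_total = c(50, 70)),
    tibble::tibble(variable = "b", category = c("b1", "b2"),
                   target_total = c(40, 80)))
  cal <- calibrate_weights(w0, df, margins)
  w <- cal$weights
  expect_equal(sum(w[df$a == "a1"]), 50, tolerance = 1e-6)
  expect_equal(sum(w[df$b == "b1"]), 40, tolerance = 1e-6)
  or0 <- (w0[1] * w0[4]) / (w0[2] * w0[3])
  or1 <- (w[1] * w[4]) / (w[2] * w[3])
  expect_equal(or1, or0, tolerance = 1e-6)
})

test_that("raking errors on uncovered or empty cells and non-convergence", {
  df <- tibble::tibble(a = c("x", "x"), w = c(1, 1))
  expect_error(
    calibrate_weights(df$w, df,
                      tibble::tibble(variable = "a", category = c("x", "y"),
                                     target_total = c(1, 1))),
    "empty sample cell")
  expect_error(
    calibrate_weights(df$w, df,
                      tibble::tibble(variable = "a", category = "z",
                                     target_total = 2)),
    "does not cover")
})

test_that("the full chain is the identity on a census with full response", {
  spec <- make_test_spec(n = 1500, severity_fraction = rep(1, 4), seed = 71)
  spec$nonresponse <- list(intercept = 30, target_rate = NULL,
                           coef = c(severity = 0, age_dec = 0,
                                    living_alone = 0))
  sv <- quiet_survey(spec)
  expect_true(all(sv$sample$responded))
  resp <- build_weights(sv$sample, margins = sv$margins)
  expect_equal(nrow(resp), spec$population_size)
  expect_equal(resp$design_weight, rep(1, nrow(resp)))
  expect_equal(resp$nonresponse_weight, rep(1, nrow(resp)))
  expect_equal(resp$calibrated_weight, rep(1, nrow(resp)), tolerance = 1e-9)
})
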