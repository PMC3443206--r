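test_that("weighted logistic fit recovers generating coefficients", {
  spec <- make_test_spec(n = 50000, k = 3, prevalence = c(0.3, 0.2, 0.25),
                         loading = rep(0.3, 3), beta = c(1.5, 1.0, 0.5),
                         intercepts = list(disabled = -2.8,
                                           severely_disabled = -4,
                                           self_reported = -2.5),
                         seed = 121)
  pop <- generate_population(spec)
  pop$w <- 1
  m <- fit_disability_model(pop, "disabled", spec$condition_names,
                            weights = "w")
  cf <- summary(m$fit)$coefficients
  est <- cf[paste0("cond_", spec$condition_names), "Estimate"]
  se <- cf[paste0("cond_", spec$condition_names), "Std. Error"]
  expect_true(all(abs(est - c(1.5, 1.0, 0.5)) < 3 * se))
  expect_lt(abs(cf["(Intercept)", "Estimate"] - (-2.8)),
            3 * cf["(Intercept)", "Std. Error"])
})

test_that("model fitting errors on constant factors and missing columns", {
  df <- tibble::tibble(y = c(1, 0, 1, 0), cond_a = c(0, 0, 0, 0), w = 1)
  expect_error(fit_disability_model(df, "y", "a", weights = "w"),
               "constant")
  expect_error(fit_disability_model(df, "y", "b", weights = "w"),
               "cond_b")
})

test_that("duplicating records while halving weights leaves the fit alone", {
  spec <- make_test_spec(n = 4000, k = 2, seed = 122)
  pop <- generate_population(spec)
  pop$w <- runif(nrow(pop), 0.5, 2)
  m1 <- fit_disability_model(pop, "disabled", spec$condition_names,
                             weights = "w")
  dup <- dplyr::bind_rows(pop, pop)
  dup$w <- dup$w / 2
  m2 <- fit_disability_model(dup, "disabled", spec$condition_names,
                             weights = "w")
  expect_equal(coef(m1$fit), coef(m2$fit), tolerance = 1e-8)
})

test_that("subset AF is zero on the empty set and for null factors", {
  spec <- make_test_spec(n = 6000, k = 2, beta = c(1.5, 0), seed = 123)
  pop <- generate_population(spec)
  pop$w <- 1
  m <- fit_disability_model(pop, "disabled", spec$condition_names,
                            weights = "w")
  expect_identical(af_of_subset(m, integer(0)), 0)
  ev <- af_subset_evaluator(m)
  # c2 truly has no effect; its fitted coefficient is near zero, so its
  # marginal contribution to any subset is near zero
  expect_lt(abs(ev(2L)), 0.02)
  expect_lt(abs(ev(1:2) - ev(1L)), 0.02)
  expect_error(af_of_subset(m, "c9"), "unknown factor")
})

test_that("single-factor saturated AF equals Levin's AF on the same table", {
  set.seed(131)
  n <- 2000
  df <- tibble::tibble(
    cond_f = as.integer(runif(n) < 0.3),
    w = runif(n, 0.5, 3))
  p <- ifelse(df$cond_f == 1, 0.35, 0.12)
  df$y <- as.integer(runif(n) < p)
  m <- fit_disability_model(df, "y", "f", weights = "w")
  af_model <- af_of_subset(m, 1L)
  pe <- sum(df$w * df$cond_f) / sum(df$w)
  rr <- estimate_rr(df$cond_f, df$y, df$w)$rr
  expect_equal(af_model, levin_af(pe, rr), tolerance = 1e-10)
  aaf_one <- aaf_exact(af_subset_evaluator(m), 1)
  expect_equal(unname(aaf_one), af_model, tolerance = 1e-12)
})

test_that("hand-computed three-factor permutation average is reproduced", {
  af <- c(0, 0.1, 0.2, 0.35, 0.3, 0.38, 0.45, 0.5)
  # order: {}, {1}, {2}, {12}, {3}, {13}, {23}, {123}
  ev <- function(s) af[(if (length(s)) sum(2^(s - 1)) else 0) + 1]
  expected <- c(53, 104, 143) / 600
  expect_equal(unname(aaf_permutation_oracle(ev, 3)), expected,
               tolerance = 1e-12)
  expect_equal(unname(aaf_exact(ev, 3)), expected, tolerance = 1e-12)
  expect_equal(sum(expected), ev(1:3))
})

test_that("exact Shapley equals the permutation oracle on random evaluators", {
  set.seed(141)
  for (k in 2:6) {
    for (rep in 1:5) {
      ev <- random_af_evaluator(k)
      expect_equal(aaf_exact(ev, k), aaf_permutation_oracle(ev, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("exchangeable factors split the joint AF equally", {
  spec <- make_test_spec(n = 30000, k = 2, prevalence = c(0.3, 0.3),
                         loading = c(0.4, 0.4), beta = c(1.5, 1.5),
                         seed = 142)
  pop <- generate_population(spec)
  pop$w <- 1
  # force exact exchangeability with a symmetric constructed model
  ev_sym <- function(s) c(0, 0.3, 0.3, 0.5)[
    (if (length(s)) sum(2^(s - 1)) else 0) + 1]
  res <- aaf_exact(ev_sym, 2)
  expect_equal(unname(res), c(0.25, 0.25), tolerance = 1e-12)
  # and near-exchangeability on fitted synthetic data
  m <- fit_disability_model(pop, "disabled", spec$condition_names,
                            weights = "w")
  est <- aaf_exact(af_subset_evaluator(m), 2, spec$condition_names)
  expect_lt(abs(est[["c1"]] - est[["c2"]]), 0.04)
})

test_that("relabeling factors permutes the AAFs identically", {
  set.seed(143)
  ev <- random_af_evaluator(4)
  base <- aaf_exact(ev, 4)
  perm <- c(3, 1, 4, 2)
  ev_perm <- function(s) ev(sort(perm[s]))
  relabeled <- aaf_exact(ev_perm, 4)
  expect_equal(unname(relabeled), unname(base[perm]), tolerance = 1e-12)
})

test_that("Monte Carlo mode is reproducible and consistent with exact", {
  set.seed(144)
  ev <- random_af_evaluator(6)
  exact <- aaf_exact(ev, 6)
  mc1 <- aaf_montecarlo(ev, 6, n_perms = 5000, seed = 7)
  mc2 <- aaf_montecarlo(ev, 6, n_perms = 5000, seed = 7)
  expect_identical(as.numeric(mc1), as.numeric(mc2))
  se <- attr(mc1, "mc_se")
  expect_true(all(abs(as.numeric(mc1) - as.numeric(exact)) <=
                    pmax(3 * se, 1e-12)))
  expect_error(aaf_montecarlo(ev, 6, n_perms = 10), "n_perms")
  # exhaustively sampling a tiny factor set converges to exact
  ev2 <- random_af_evaluator(2)
  mc_small <- aaf_montecarlo(ev2, 2, n_perms = 4000, seed = 8)
  expect_equal(as.numeric(mc_small), as.numeric(aaf_exact(ev2, 2)),
               tolerance = 0.05)
})

test_that("expected prevented counts multiply and round as reported", {
  ep <- expected_prevented(0.174, 1836753)
  expect_equal(ep$raw, 319595.022, tolerance = 1e-6)
  expect_equal(ep$rounded, 320000)
  ep2 <- expected_prevented(0.310, 673199)
  expect_equal(ep2$raw, 208691.69, tolerance = 1e-6)
  expect_equal(ep2$rounded, 210000)
  expect_equal(expected_prevented(0, 5000)$raw, 0)
})

test_that("the high-level estimator satisfies efficiency and dummy axioms", {
  spec <- make_test_spec(n = 12000, k = 3, prevalence = c(0.3, 0.2, 0.25),
                         loading = rep(0.3, 3), beta = c(1.5, 1.0, 0),
                         seed = 151)
  sv <- quiet_survey(spec)
  resp <- build_weights(sv$sample, margins = sv$margins)
  res <- aaf(resp, "disabled", spec$condition_names,
             covariates = c("sex", "age_class"))
  expect_equal(sum(res$aaf), attr(res, "af_all"), tolerance = 1e-9)
  expect_lt(abs(res$aaf[res$factor == "c3"]), 0.02)
  expect_equal(res$rank, rank(-res$aaf, ties.method = "min"))
  expect_equal(res$prevented_raw, res$aaf * attr(res, "n_disabled"))
})
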