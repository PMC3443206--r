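test_that("spec validation names the offending field", {
  expect_error(make_test_spec(prevalence = c(0.3, 1.2)),
               "marginal_prevalence")
  expect_error(make_test_spec(loading = c(0, 1.5)), "comorbidity_loading")
  expect_error(population_spec(design = list(n_areas = 2,
                                             severity_fraction = c(0.1, 0.2),
                                             area_multiplier = c(1, 1),
                                             mode = "bernoulli")),
               "severity_fraction")
  expect_error(population_spec(condition_names = c("a", "a"),
                               marginal_prevalence = c(a = 0.1, a = 0.1)),
               "unique")
})

test_that("zero loadings give independent conditions with exact marginals", {
  spec <- make_test_spec(n = 20000, k = 4,
                         prevalence = c(0.1, 0.25, 0.4, 0.6),
                         loading = rep(0, 4), seed = 11)
  pop <- generate_population(spec)
  cond <- as.matrix(pop[paste0("cond_", spec$condition_names)])
  r <- cor(cond)
  expect_true(all(abs(r[upper.tri(r)]) < 3 / sqrt(nrow(pop))))
  p_hat <- colMeans(cond)
  mc <- 3 * sqrt(spec$marginal_prevalence * (1 - spec$marginal_prevalence) /
                   nrow(pop))
  expect_true(all(abs(p_hat - spec$marginal_prevalence) < mc))
})

test_that("positive loadings induce nonnegative pairwise correlations", {
  spec <- make_test_spec(n = 20000, k = 4, prevalence = rep(0.3, 4),
                         loading = rep(0.6, 4), seed = 12)
  pop <- generate_population(spec)
  r <- cor(as.matrix(pop[paste0("cond_", spec$condition_names)]))
  expect_true(all(r[upper.tri(r)] > 0))
})

test_that("degenerate specs behave as documented", {
  # prevalence zero: condition never occurs
  spec0 <- make_test_spec(n = 2000, k = 1, prevalence = 0, seed = 13)
  pop0 <- generate_population(spec0)
  expect_equal(sum(pop0$cond_c1), 0)

  # hugely negative intercepts: nobody disabled, severity all 1
  spec_neg <- make_test_spec(
    n = 2000, k = 1, prevalence = 0.3,
    intercepts = list(disabled = -30, severely_disabled = -30,
                      self_reported = -30), seed = 14)
  pop_neg <- generate_population(spec_neg)
  expect_equal(sum(pop_neg$disabled), 0)
  expect_true(all(pop_neg$presumed_severity == 1L))
  expect_true(all(as.matrix(pop_neg[paste0("adl_", 1:6)]) == 0))
})

test_that("fixed seed reproduces identical populations and samples", {
  spec <- make_test_spec(n = 3000, seed = 21)
  expect_identical(generate_population(spec), generate_population(spec))
  pop <- generate_population(spec)
  expect_identical(draw_sample(pop, spec), draw_sample(pop, spec))
})

test_that("census sampling returns the population with unit weights", {
  spec <- make_test_spec(n = 1000, severity_fraction = rep(1, 4), seed = 22)
  pop <- generate_population(spec)
  s <- draw_sample(pop, spec)
  expect_equal(nrow(s), nrow(pop))
  expect_true(all(s$design_weight == 1))
})

test_that("design weights are the inverse sampling fraction", {
  spec <- make_test_spec(n = 4000, severity_fraction = c(0.1, 0.2, 0.5, 0.9),
                         seed = 23)
  pop <- generate_population(spec)
  s <- draw_sample(pop, spec)
  sev1 <- s[s$presumed_severity == 1, ]
  expect_true(all(sev1$design_weight == 10))
  expect_equal(s$design_weight, 1 / s$sampling_fraction)
})

test_that("Horvitz-Thompson weighted totals are unbiased over seeds", {
  spec <- make_test_spec(n = 2000, severity_fraction = c(0.05, 0.2, 0.5, 0.9),
                         seed = 24)
  pop <- generate_population(spec)
  totals <- vapply(1:50, function(i) {
    sum(draw_sample(pop, spec, seed = 1000 + i)$design_weight)
  }, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - nrow(pop)), 3 * se)
})

test_that("fixed-size stratified sampling hits the per-stratum counts", {
  spec <- make_test_spec(n = 4000, seed = 25)
  spec$design$mode <- "fixed"
  pop <- generate_population(spec)
  s <- draw_sample(pop, spec)
  for (st in unique(pop$stratum_id)) {
    n_pop <- sum(pop$stratum_id == st)
    f <- s$sampling_fraction[s$stratum_id == st][1]
    expect_equal(sum(s$stratum_id == st), round(f * n_pop))
  }
})

test_that("non-response follows the logistic model", {
  # intercept-only response model
  spec <- make_test_spec(n = 8000, seed = 26)
  spec$nonresponse <- list(intercept = qlogis(0.7), target_rate = NULL,
                           coef = c(severity = 0, age_dec = 0,
                                    living_alone = 0))
  pop <- generate_population(spec)
  s <- suppressMessages(apply_nonresponse(draw_sample(pop, spec), spec))
  rate <- mean(s$responded)
  expect_lt(abs(rate - 0.7), 3 * sqrt(0.7 * 0.3 / nrow(s)))

  # severity coefficient drives the rate in the stated direction
  spec2 <- make_test_spec(n = 20000, k = 1, beta = 2, prevalence = 0.3,
                          seed = 27)
  spec2$nonresponse <- list(intercept = qlogis(0.8), target_rate = NULL,
                            coef = c(severity = -0.8, age_dec = 0,
                                     living_alone = 0))
  pop2 <- generate_population(spec2)
  s2 <- suppressMessages(apply_nonresponse(draw_sample(pop2, spec2), spec2))
  r_by_sev <- tapply(s2$responded, s2$presumed_severity, mean)
  expect_lt(r_by_sev[["4"]], r_by_sev[["1"]])
})

test_that("response rate calibrates to the 76.6% default target", {
  spec <- make_test_spec(n = 30000, seed = 28, response_target = 0.766)
  pop <- generate_population(spec)
  s <- suppressMessages(apply_nonresponse(draw_sample(pop, spec), spec))
  mc <- 3 * sqrt(0.766 * (1 - 0.766) / nrow(s))
  expect_lt(abs(mean(s$responded) - 0.766), mc)
})

test_that("oracle single-condition AAF equals Levin closed form", {
  spec <- make_test_spec(n = 20000, k = 1, prevalence = 0.25, beta = 1.2,
                         intercepts = list(disabled = -2.5,
                                           severely_disabled = -3.5,
                                           self_reported = -2.2),
                         seed = 31)
  pop <- generate_population(spec)
  tr <- true_aaf_oracle(spec, "disabled", population = pop)
  # brute force over the four exposure x outcome cells of the generating
  # model: expected cases n1*p1 + n0*p0, unexposed risk p0
  p1 <- plogis(-2.5 + 1.2); p0 <- plogis(-2.5)
  pe <- mean(pop$cond_c1)
  af_cells <- 1 - p0 / (pe * p1 + (1 - pe) * p0)
  rr <- p1 / p0
  expect_equal(unname(tr[["c1"]]), af_cells, tolerance = 1e-12)
  expect_equal(af_cells, levin_af(pe, rr), tolerance = 1e-12)
})

test_that("oracle symmetry, dummy and efficiency properties hold", {
  spec <- make_test_spec(n = 30000, k = 2, prevalence = c(0.3, 0.3),
                         loading = c(0.4, 0.4), beta = c(1.5, 1.5), seed = 32)
  pop <- generate_population(spec)
  tr <- true_aaf_oracle(spec, "disabled", population = pop)
  # exchangeable conditions: equal AAFs up to finite-population noise
  expect_equal(unname(tr[["c1"]]), unname(tr[["c2"]]), tolerance = 0.02)
  expect_equal(sum(tr), attr(tr, "af_all"), tolerance = 1e-10)

  spec0 <- make_test_spec(n = 5000, k = 2, beta = c(1.5, 0), seed = 33)
  tr0 <- true_aaf_oracle(spec0, "disabled")
  expect_equal(unname(tr0[["c2"]]), 0, tolerance = 1e-12)
  expect_error(true_aaf_oracle(spec0, "disabled",
                               conditions = paste0("x", 1:13)), "k <= 12")
})

test_that("severe disability always implies disability in generated data", {
  spec <- make_test_spec(n = 10000, k = 3, beta = c(2, 1, 0.5),
                         loading = rep(0.5, 3), seed = 34)
  pop <- generate_population(spec)
  expect_true(all(pop$disabled[pop$severely_disabled]))
  st <- classify_disability(pop[paste0("adl_", 1:6)], pop$self_report)
  expect_identical(st$disabled, pop$disabled)
  expect_identical(st$severely_disabled, pop$severely_disabled)
})
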