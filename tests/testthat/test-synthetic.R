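test_that("configs are validated and generation is reproducible", {
  expect_error(sim_config(n = 0), "positive count")
  expect_error(sim_config(prevalence_targets = list(boy = c(thinness = 1.2,
                                                            stunting = 0.2),
                                                    girl = c(thinness = 0.1,
                                                             stunting = 0.2))),
               "\\(0, 1\\)")
  expect_error(sim_config(sex_ratio = 1.5), "sex_ratio")
  cfg <- sim_config(n = 800, seed = 99)
  expect_identical(generate_population(cfg), generate_population(cfg))
  # a different seed changes the draw
  expect_false(identical(generate_population(cfg),
                         generate_population(sim_config(n = 800, seed = 100))))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(generate_population(sim_config(n = 50, seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("achieved prevalences hit their targets", {
  cfg <- sim_config(n = 20000, seed = 5,
                    prevalence_targets = list(
                      boy = c(thinness = 0.25, stunting = 0.30),
                      girl = c(thinness = 0.25, stunting = 0.30)))
  pop <- generate_population(cfg)
  p <- mean(pop$thinness)
  expect_gte(p, 0.24); expect_lte(p, 0.26)
  s <- mean(pop$stunting)
  expect_gte(s, 0.29); expect_lte(s, 0.31)
})

test_that("wealth quintiles split total weight evenly under equal weights", {
  pop <- generate_population(sim_config(n = 4003, seed = 12))
  counts <- table(pop$wealth_quintile)
  expect_equal(length(counts), 5L)
  expect_lte(diff(range(counts)), 2)   # 20% each, +/- 1 record
})

test_that("stored flags equal flags regenerated from the stored z-scores", {
  pop <- generate_population(sim_config(n = 3000, seed = 8))
  f <- classify_nutrition(pop$z_bmi_age, pop$z_height_age)
  expect_equal(pop$thinness, f$thinness)
  expect_equal(pop$stunting, f$stunting)
  expect_equal(pop$both, f$both)
  expect_true(all(pop$both <= pmin(pop$thinness, pop$stunting)))
})

test_that("tie injection and variable weights behave as requested", {
  pop <- generate_population(sim_config(n = 1000, seed = 4,
                                        tie_fraction = 0.2))
  expect_gte(sum(duplicated(pop$wealth_score)), 0.08 * 1000)
  popw <- generate_population(sim_config(n = 500, seed = 4,
                                         weight_scheme = "variable"))
  expect_true(all(popw$weight > 0))
  expect_gt(stats::sd(popw$weight), 0)
  # wealth score is continuous: no mass points unless ties requested
  pop0 <- generate_population(sim_config(n = 5000, seed = 4))
  expect_equal(sum(duplicated(pop0$wealth_score)), 0)
})

test_that("with no socioeconomic gradient the outcome indices vanish", {
  pop <- generate_population(sim_config(n = 20000, seed = 14,
                                        gradient_strength = 0))
  for (oc in c("thinness", "stunting")) {
    ci <- concentration(pop[[oc]], pop$wealth_score)$index
    expect_lt(abs(ci), 0.02)
  }
})

test_that("the LPM generator enforces its mean structure and ground truth", {
  dists <- list(rich = list(kind = "rank_gt", threshold = 0.8),
                other = list(kind = "bernoulli", p = 0.3, slope = 1))
  # all betas zero: every contribution is zero and prevalence is alpha
  d0 <- generate_lpm_population(0.2, c(rich = 0, other = 0), dists,
                                n = 50000, seed = 2)
  expect_true(all(abs(attr(d0, "ground_truth")$absolute) < 1e-12))
  expect_lt(abs(mean(d0$outcome) - 0.2), 0.01)
  res0 <- ci_decomp(outcome ~ rich + other, d0, score = "wealth_score")
  expect_true(all(abs(res0$rows$absolute) < 0.01, na.rm = TRUE))

  # OLS recovers a true coefficient within 3 standard errors
  d1 <- generate_lpm_population(0.15, c(rich = 0.2, other = 0.05), dists,
                                n = 20000, seed = 3)
  fit <- summary(lm(outcome ~ rich + other, data = d1))$coefficients
  expect_lt(abs(fit["rich", "Estimate"] - 0.2), 3 * fit["rich", "Std. Error"])
  expect_equal(attr(d1, "clip_rate"), 0)

  # infeasible configurations are rejected, heavy clipping warns
  expect_error(generate_lpm_population(1.4, c(rich = 0, other = 0), dists,
                                       n = 100, seed = 1), "infeasible")
  expect_warning(generate_lpm_population(0.9, c(rich = 0.5, other = 0), dists,
                                         n = 2000, seed = 1), "clipped")
})

test_that("the LMS fixture is a valid reference exercising both branches", {
  fix <- make_lms_fixture()
  expect_gte(length(unique(fix$sex)), 2)
  expect_gte(length(unique(fix$age_months)), 5)
  expect_setequal(unique(fix$indicator), c("bmi_age", "height_age"))
  expect_true(any(fix$L == 0))
  row <- lookup_reference(fix, "boy", 132, "bmi_age")
  expect_equal(row, c(L = 1, M = 16.0, S = 0.1))
  expect_error(load_growth_reference(textConnection("sex,age_months\nboy,120")),
               "missing column")
})
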