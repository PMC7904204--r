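test_that("elasticity is beta times covariate mean over outcome mean", {
  expect_equal(elasticity(0, 0.4, 0.2), 0)
  expect_equal(elasticity(0.5, 0.4, 0.2), 1)
  expect_equal(elasticity(1, 0.3, 0.3), 1)
  expect_error(elasticity(0.5, 0.4, 0), "mean is zero")
})

test_that("covariate concentration index mirrors the outcome estimator", {
  r <- fractional_rank(1:10)
  x <- as.numeric(r > 0.8)
  expect_equal(covariate_ci(x, r), concentration_index(x, r))
  expect_equal(covariate_ci(rep(1, 10), r), 0)  # constant dummy
  # symmetry: bottom-quintile dummy is the negative of the top-quintile one
  expect_equal(covariate_ci(as.numeric(r < 0.2), r),
               -covariate_ci(as.numeric(r > 0.8), r))
})

test_that("explained plus residual equals the actual index exactly", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      d <- small_factor_data(300)
      res <- ci_decomp(y ~ g1 + g2, d, score = "score")
      expect_lt(abs(res$calculated_ci + res$residual - res$actual_ci), 1e-10)
      expect_equal(sum(res$rows$pct, na.rm = TRUE), 100, tolerance = 1e-8)
      expect_equal(sum(res$group_totals), 100, tolerance = 1e-8)
    }
  })
})

test_that("an intercept-only model leaves everything in the residual", {
  d <- small_factor_data(400, seed = 55)
  res <- ci_decomp(y ~ 1, d, score = "score")
  expect_equal(res$calculated_ci, 0)
  expect_equal(res$residual, res$actual_ci, tolerance = 1e-12)
  expect_equal(nrow(res$rows), 0)
})

test_that("a noiseless single-covariate outcome is fully explained", {
  withr::with_seed(77, {
    s <- rnorm(500)
    r <- fractional_rank(s)
    x <- ifelse(r > 0.6, "top", "bottom")
    d <- data.frame(y = as.numeric(x == "top"), x = x, score = s)
    res <- ci_decomp(y ~ x, d, score = "score",
                     specs = list(factor_spec("x", c("bottom", "top"))))
    expect_equal(res$residual, 0, tolerance = 1e-12)
    expect_equal(res$rows$absolute[res$rows$category == "top"],
                 res$actual_ci, tolerance = 1e-12)
    expect_equal(res$rows$elasticity[res$rows$category == "top"], 1)
  })
})

test_that("contributions have coherent signs and ignore factor order", {
  withr::with_seed(88, {
    s <- rnorm(2000)
    r <- fractional_rank(s)
    rich <- rbinom(2000, 1, plogis(-1 + 3 * (r - 0.5)))   # C_k > 0
    other <- sample(c("m", "n"), 2000, replace = TRUE)
    y <- rbinom(2000, 1, 0.2 + 0.3 * rich)                # beta > 0
    d <- data.frame(y = y, rich = rich, other = other, score = s)
    a <- ci_decomp(y ~ rich + other, d, score = "score")
    b <- ci_decomp(y ~ other + rich, d, score = "score")
    row_a <- a$rows[a$rows$factor == "rich" & a$rows$category == "1", ]
    expect_gt(row_a$absolute, 0)          # beta>0, C_k>0, mu>0
    row_b <- b$rows[b$rows$factor == "rich" & b$rows$category == "1", ]
    expect_equal(row_a$absolute, row_b$absolute)
    expect_equal(sort(a$group_totals), sort(b$group_totals))
    expect_equal(a$actual_ci, b$actual_ci)
  })
})

test_that("empty categories contribute zero without breaking the fit", {
  d <- small_factor_data(200, seed = 60)
  specs <- list(factor_spec("g1", c("a", "b", "c", "ghost")),
                factor_spec("g2", c("u", "v")))
  res <- ci_decomp(y ~ g1 + g2, d, score = "score", specs = specs)
  ghost <- res$rows[res$rows$category == "ghost", ]
  expect_equal(ghost$absolute, 0)
  expect_true(is.na(ghost$ci_k))
  expect_lt(abs(res$calculated_ci + res$residual - res$actual_ci), 1e-10)
})

test_that("the logit engine approximates the OLS decomposition", {
  d <- small_factor_data(1500, seed = 62)
  ols <- ci_decomp(y ~ g1 + g2, d, score = "score")
  lgt <- ci_decomp(y ~ g1 + g2, d, score = "score", engine = "logit")
  expect_equal(lgt$actual_ci, ols$actual_ci)
  # identity still holds by construction of the residual
  expect_lt(abs(lgt$calculated_ci + lgt$residual - lgt$actual_ci), 0.02)
  expect_equal(lgt$engine, "logit")
})

test_that("formatted tables round half away from zero at table precision", {
  expect_equal(round_half_up(-0.02334, 3), -0.023)
  expect_equal(round_half_up(0.0005, 3), 0.001)
  expect_equal(round_half_up(-0.0005, 3), -0.001)
  expect_equal(round_half_up(2084 / 5969 * 100, 1), 34.9)

  d <- small_factor_data(800, seed = 91)
  res <- ci_decomp(y ~ g1 + g2, d, score = "score")
  tab <- decomp_table(res)
  foot <- tab[tab$factor %in% c("Calculated CI", "Actual CI", "Residual"), ]
  expect_equal(nrow(foot), 3)
  # residual row equals actual minus calculated at printed precision
  printed <- as.numeric(foot$absolute)
  expect_lt(abs(printed[3] - (printed[2] - printed[1])), 0.0011)
  # reference rows blank, percentage totals accumulate to ~100
  expect_equal(tab$elasticity[tab$category == "a"], "")
  gt <- as.numeric(tab$group_total[tab$group_total != ""])
  expect_lt(abs(sum(gt) - 100), 0.3)
})

test_that("decomposition objects support the standard model methods", {
  d <- small_factor_data(500, seed = 70)
  res <- ci_decomp(y ~ g1 + g2, d, score = "score")
  expect_named(coef(res)[1], "(Intercept)")
  expect_length(residuals(res), res$n)
  expect_equal(fitted(res) + residuals(res), d$y[!is.na(d$y)])
  expect_equal(predict(res, d[1:10, ]), fitted(res)[1:10])
  sims <- simulate(res, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(res$n, 3))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_output(print(res), "Actual CI")
  expect_output(print(summary(res)), "Adding-up gap")
})
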