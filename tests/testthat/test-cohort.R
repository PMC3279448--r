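test_that("growth categories partition (0,100) with strict SGA/LGA bounds", {
  expect_equal(as.character(classify_growth(c(5, 10, 50, 90, 95))),
               c("SGA", "AGA", "AGA", "AGA", "LGA"))
  expect_error(classify_growth(0), "strictly inside")
  expect_error(classify_growth(100), "strictly inside")
  # exhaustive and disjoint over a fine grid
  grid <- seq(0.01, 99.99, by = 0.01)
  cats <- classify_growth(grid)
  expect_false(anyNA(cats))
  expect_equal(sum(cats == "SGA"), sum(grid < 10))
  expect_equal(sum(cats == "LGA"), sum(grid > 90))
})

test_that("case-control matching honours windows and tie rules", {
  case <- toy_subjects("C1", "female", 30, 275)
  ok_pool <- toy_subjects("P1", "female", 32, 276)
  m <- match_controls(case, ok_pool)
  expect_equal(m$control_id, "P1")

  # age outside +/- 3 years -> unmatched
  far_pool <- toy_subjects("P1", "female", 34, 275)
  expect_true(is.na(match_controls(case, far_pool)$control_id))

  # wrong sex -> unmatched
  sex_pool <- toy_subjects("P1", "male", 30, 275)
  expect_true(is.na(match_controls(case, sex_pool)$control_id))

  # gestational age outside +/- 2 days -> unmatched
  ga_pool <- toy_subjects("P1", "female", 30, 278)
  expect_true(is.na(match_controls(case, ga_pool)$control_id))

  # exact copies: every case matched, controls used at most once
  cases <- toy_subjects("C1", "female", 25, 270,
                        "C2", "male", 30, 275,
                        "C3", "female", 35, 280,
                        "C4", "male", 28, 272,
                        "C5", "female", 22, 268)
  pool <- cases
  pool$subject_id <- sub("C", "P", pool$subject_id)
  m5 <- match_controls(cases, pool)
  expect_equal(sum(!is.na(m5$control_id)), 5)
  expect_false(anyDuplicated(m5$control_id) > 0)

  # nearest age wins; ties broken by gestational age, then ID
  pool2 <- toy_subjects("P1", "female", 32, 275,
                        "P2", "female", 31, 277,
                        "P3", "female", 31, 276)
  expect_equal(match_controls(case, pool2)$control_id, "P3")
})

test_that("Kruskal-Wallis agrees with the rank-formula oracle", {
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(kruskal_wallis(v, g)$statistic, oracle_kruskal_h(v, g),
               tolerance = 1e-12)

  # with ties
  v2 <- c(1, 2, 2, 4, 5, 5, 7, 8)
  g2 <- rep(c("a", "b"), each = 4)
  expect_equal(kruskal_wallis(v2, g2)$statistic, oracle_kruskal_h(v2, g2),
               tolerance = 1e-12)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two groups")
})

test_that("Kruskal-Wallis holds its nominal level under the null", {
  set.seed(17)
  p <- replicate(400, {
    kruskal_wallis(rnorm(30), rep(c("a", "b", "c"), each = 10))$p_value
  })
  expect_gt(mean(p <= 0.05), 0.02)
  expect_lt(mean(p <= 0.05), 0.09)
})

test_that("chi-square matches hand arithmetic", {
  flat <- chi_square(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1, tolerance = 1e-12)

  # [[20,10],[10,20]]: all expected 15, sum((O-E)^2/E) = 4 * 25/15
  res <- chi_square(matrix(c(20, 10, 10, 20), 2))
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)

  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "expected")
})

test_that("Fisher-z interval reproduces the r = 0.29, n = 380 case", {
  # construct vectors with exactly the target sample correlation
  set.seed(23)
  x <- rnorm(380)
  z <- rnorm(380)
  z <- residuals(lm(z ~ x))
  y <- 0.29 * scale(x)[, 1] + sqrt(1 - 0.29^2) * scale(z)[, 1]
  ci <- pearson_ci(x, y)
  expect_equal(ci$r, 0.29, tolerance = 1e-10)
  expect_equal(round(ci$conf_low, 2), 0.20)
  expect_equal(round(ci$conf_high, 2), 0.38)

  expect_equal(pearson_ci(1:10, 1:10)$r, 1)
  expect_equal(pearson_ci(1:10, 10:1)$r, -1)
  expect_error(pearson_ci(rep(1, 10), 1:10), "constant")
})

test_that("birth-weight model recovers a noiseless per-10% effect exactly", {
  set.seed(41)
  co <- simulate_cohort(sim_config(n_subjects = 120, seed = 41))
  co$birthweight_percentile <- pmin(pmax(0.97 * co$line1, 0.1), 99.9)
  # small cohorts can have no alcohol users; the constant-column warning
  # is expected and irrelevant to the recovery check
  fit <- suppressWarnings(fit_birthweight_model(co, "line1"))
  est <- suppressWarnings(tidy(fit))  # lm warns on a perfect fit
  expect_equal(est$estimate[est$term == "line1 (per 10%)"], 9.7,
               tolerance = 1e-8)
})

test_that("collinear designs error with the aliased terms named", {
  co <- simulate_cohort(sim_config(n_subjects = 100, seed = 43))
  co$alcohol <- co$tobacco  # duplicated indicator -> aliased
  expect_error(suppressWarnings(fit_birthweight_model(co, "line1")),
               "aliased|collinear")
})

test_that("OLS residuals are orthogonal to the design", {
  co <- simulate_cohort(sim_config(n_subjects = 200, seed = 47))
  fit <- fit_birthweight_model(co, "aluyb8")
  X <- model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(X, residuals(fit$fit)))), 1e-7)
})

test_that("confidence intervals cover a null effect at the nominal rate", {
  cfg0 <- sim_config(n_subjects = 150, effect_line1_per10 = 0,
                     effect_alu_per10 = 0)
  covered <- vapply(1:40, function(s) {
    co <- simulate_cohort(cfg0, seed = 100 + s)
    td <- suppressWarnings(tidy(fit_birthweight_model(co, "line1")))
    row <- td[td$term == "line1 (per 10%)", ]
    row$conf_low <= 0 && row$conf_high >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
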