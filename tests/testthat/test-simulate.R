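test_that("marker correlation follows the configured value", {
  # independence when configured correlation is zero
  cors0 <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(marker_correlation = 0, seed = s))
    cor(co$line1, co$aluyb8)
  }, numeric(1))
  expect_lt(abs(mean(cors0)), 0.03)

  # calibrated default lands on the target scale
  cors <- vapply(1:15, function(s) {
    co <- simulate_cohort(sim_config(seed = s))
    cor(co$line1, co$aluyb8)
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.29), 0.07)
})

test_that("degenerate noise collapses percentiles to the baseline", {
  cfg <- sim_config(effect_line1_per10 = 0, effect_alu_per10 = 0,
                    effect_male_sex = 0, effect_white_ethnicity = 0,
                    residual_sd = 1e-9, seed = 3)
  co <- simulate_cohort(cfg)
  expect_true(all(abs(co$birthweight_percentile - 50) < 1e-6))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(residual_sd = 0), "residual_sd")
  expect_error(sim_config(residual_sd = -1), "residual_sd")
  expect_error(sim_config(marker_correlation = 1), "marker_correlation")
  expect_error(sim_config(class_precision = -5), "positive")
  expect_error(sim_config(class_means = rep(0.5, 16)), "increasing")
  expect_error(
    sim_config(attribute_frequencies = c(cgi = 0.5, pcg = 0.1, tfbs = 0.5,
                                         alu = 0.5, line1 = 0.3,
                                         line2 = 0.2, mir = 0.2)),
    "sum")
})

test_that("beta matrix reflects its latent-class specification", {
  # single symmetric class: matrix mean near 0.5
  cfg1 <- sim_config(n_loci = 300, n_latent_classes = 1, class_means = 0.5,
                     class_precision = 100, class_props = 1, seed = 5)
  sim1 <- simulate_beta_matrix(cfg1, n_subjects = 20)
  expect_lt(abs(mean(sim1$beta) - 0.5), 0.01)

  # 16 separated classes: empirical class means strictly increase
  sim16 <- simulate_beta_matrix(sim_config(seed = 7), n_subjects = 30)
  cl_means <- vapply(1:16, function(k) {
    mean(sim16$beta[sim16$truth$latent_class == k, , drop = FALSE])
  }, numeric(1))
  expect_true(all(diff(cl_means) > 0))

  # default matrix-wide mean on the array scale
  expect_gt(mean(sim16$beta), 0.2)
  expect_lt(mean(sim16$beta), 0.3)

  # values always inside [0, 1]
  expect_true(all(sim16$beta >= 0 & sim16$beta <= 1))
})

test_that("annotation respects configured attribute frequencies", {
  cfg0 <- sim_config(n_loci = 200,
                     attribute_frequencies = c(cgi = 0, pcg = 0, tfbs = 0,
                                               alu = 0, line1 = 0,
                                               line2 = 0, mir = 0),
                     seed = 2)
  ann0 <- simulate_annotation(cfg0)
  expect_false(any(ann0$cgi | ann0$pcg_target | ann0$tfbs |
                     ann0$rep_alu | ann0$rep_line1 | ann0$rep_line2 |
                     ann0$rep_mir))
  expect_true(all(lengths(ann0$tfbs_factors) == 0))

  # class-dependent CGI enrichment
  cfg <- sim_config(n_loci = 4000, seed = 9)
  sim <- simulate_beta_matrix(cfg, n_subjects = 5)
  ann <- simulate_annotation(cfg, labels = sim$truth$latent_class,
                             class_overrides = list(cgi = c("9" = 0.81)),
                             seed = 10)
  frac9 <- mean(ann$cgi[sim$truth$latent_class == 9])
  expect_lt(abs(frac9 - 0.81), 0.08)

  # TFBS sets nonempty iff flag set
  expect_true(all((lengths(ann$tfbs_factors) > 0) == ann$tfbs))
})

test_that("generators are seed-reproducible and seeds matter", {
  cfg <- sim_config(n_loci = 100, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_beta_matrix(cfg)$beta,
                   simulate_beta_matrix(cfg)$beta)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  expect_false(identical(simulate_cohort(cfg, seed = 1),
                         simulate_cohort(cfg, seed = 2)))
})

test_that("empirical moments converge to configured moments", {
  cfg <- sim_config(n_subjects = 10000, seed = 13)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$line1) - 51.7), 0.2)
  expect_lt(abs(sd(co$line1) - 4.6), 0.2)
  expect_lt(abs(mean(co$aluyb8) - 65.0), 0.2)
  expect_lt(abs(cor(co$line1, co$aluyb8) - 0.29), 0.03)
  expect_lt(abs(mean(co$tobacco) - 36 / 380), 0.02)
  expect_true(all(co$birthweight_percentile > 0 &
                    co$birthweight_percentile < 100))
  expect_true(all(co$line1 >= 0 & co$line1 <= 100))
})
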