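null_aggregates <- function(n_subj = 40, k = 8, seed = 91) {
  set.seed(seed)
  Y <- matrix(rbeta(n_subj * k, 5, 15), n_subj, k)
  out <- tibble::as_tibble(as.data.frame(Y))
  names(out) <- as.character(seq_len(k))
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%03d",
                                                       seq_len(n_subj))),
                   out)
}

test_that("a noiseless linear aggregate gives the capped t and exact slope", {
  marker <- seq(40, 70, length.out = 20)
  agg <- tibble::tibble(subject_id = sprintf("S%02d", 1:20),
                        lin = 0.01 * marker)
  suppressWarnings(res <- class_regressions(agg, marker))
  expect_equal(res$slope, 0.1)  # 0.01 per unit = 0.1 per 10%
  expect_equal(res$t, 1e8)      # perfect fit hits the cap
})

test_that("constant aggregates yield t = 0 with a warning", {
  marker <- rnorm(20, 50, 4)
  agg <- tibble::tibble(subject_id = sprintf("S%02d", 1:20),
                        flat = rep(0.3, 20))
  expect_warning(res <- class_regressions(agg, marker), "constant")
  expect_equal(res$t, 0)
  expect_error(class_regressions(agg[1:2, ], marker[1:2]), "10 subjects")
})

test_that("per-class t follows Student's t under independence", {
  set.seed(97)
  n <- 30
  ts <- replicate(400, {
    agg <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                          a = rbeta(n, 4, 12))
    class_regressions(agg, rnorm(n, 50, 5))$t
  })
  ks <- ks.test(ts, function(q) pt(q, df = n - 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("class regressions agree with lm on each class", {
  set.seed(101)
  agg <- null_aggregates()
  marker <- rnorm(40, 50, 5)
  res <- class_regressions(agg, marker)
  for (k in c("1", "4", "8")) {
    fit <- summary(lm(agg[[k]] ~ I(marker / 10)))
    expect_equal(res$slope[res$class == k], fit$coefficients[2, 1],
                 tolerance = 1e-10)
    expect_equal(res$t[res$class == k], fit$coefficients[2, 3],
                 tolerance = 1e-8)
  }
})

test_that("omnibus p-value behaves as an add-one estimator", {
  set.seed(103)
  agg <- null_aggregates(n_subj = 30, k = 4, seed = 103)
  marker <- 50 + 40 * (agg[["2"]] - mean(agg[["2"]])) + rnorm(30, 0, 0.2)
  ot <- max_t_permutation(agg, marker, B = 200, seed = 5)
  expect_equal(ot$p_value, 1 / 201)  # observed beats every permutation
  expect_gt(ot$p_value, 0)
  expect_true(ot$per_class$significant[ot$per_class$class == "2"])
  expect_equal(max(abs(ot$per_class$t)), ot$max_t)

  expect_error(max_t_permutation(agg, marker, B = 50), "at least 100")
})

test_that("permutation streams are seed-reproducible and the observed
           statistic ignores B", {
  agg <- null_aggregates(seed = 107)
  marker <- rnorm(40, 50, 5)
  o1 <- max_t_permutation(agg, marker, B = 150, seed = 9)
  o2 <- max_t_permutation(agg, marker, B = 150, seed = 9)
  expect_identical(o1$null_max_t, o2$null_max_t)
  o3 <- max_t_permutation(agg, marker, B = 400, seed = 10)
  expect_equal(o1$max_t, o3$max_t)  # observed statistic independent of B
})

test_that("with one class the omnibus approximates the single-regression
           permutation test", {
  set.seed(109)
  n <- 30
  agg <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                        a = rbeta(n, 4, 12))
  marker <- rnorm(n, 50, 5)
  marker <- marker + 18 * (agg$a - mean(agg$a))
  ot <- max_t_permutation(agg, marker, B = 1000, seed = 11)
  # independent oracle: plain permutation of |t| for one regression
  t_obs <- abs(summary(lm(agg$a ~ marker))$coefficients[2, 3])
  set.seed(12)
  t_null <- replicate(1000, {
    abs(summary(lm(agg$a ~ sample(marker)))$coefficients[2, 3])
  })
  p_oracle <- (1 + sum(t_null >= t_obs)) / 1001
  expect_lt(abs(ot$p_value - p_oracle), 0.05)
})

test_that("null limits flag exactly the classes beyond them", {
  agg <- null_aggregates(seed = 113)
  ot <- max_t_permutation(agg, rnorm(40, 50, 5), B = 200, seed = 13)
  expect_equal(ot$per_class$significant,
               abs(ot$per_class$t) > ot$null_limit)
  expect_true(ot$p_value > 0 && ot$p_value <= 1)
})

test_that("autoplot returns a ggplot with the null-limit layers", {
  agg <- null_aggregates(seed = 127)
  ot <- max_t_permutation(agg, rnorm(40, 50, 5), B = 100, seed = 14)
  p <- autoplot(ot, aggregates = agg)
  expect_s3_class(p, "ggplot")
})
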