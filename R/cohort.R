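#' Classify birth weight percentile into growth categories
#'
#' Small for gestational age (SGA) is a birth weight strictly below the
#' 10th percentile for gestational age; large for gestational age (LGA) is
#' strictly above the 90th; everything between (inclusive of the
#' boundaries) is appropriate for gestational age (AGA).
#'
#' @param percentile Numeric vector of birth weight percentiles in
#'   `(0, 100)`.
#' @return Factor with levels `SGA`, `AGA`, `LGA`.
#' @examples
#' classify_growth(c(5, 10, 50, 90, 95))
#' @export
classify_growth <- function(percentile) {
  if (any(!is.finite(percentile)) ||
      any(percentile <= 0 | percentile >= 100)) {
    abort("birth weight percentile must lie strictly inside (0, 100)")
  }
  factor(ifelse(percentile < 10, "SGA",
                ifelse(percentile > 90, "LGA", "AGA")),
         levels = c("SGA", "AGA", "LGA"))
}

#' Match SGA cases to non-SGA controls
#'
#' Greedy deterministic 1:1 matching: each SGA case is paired with an
#' unused non-SGA control of the same infant sex with maternal age within
#' +/- 3 years and gestational age within +/- 2 days. Cases are processed
#' in ID order; among eligible controls the one with the smallest maternal
#' age difference is chosen, ties broken by smallest gestational-age
#' difference, then lowest control ID. Unmatched cases are reported, not
#' fatal.
#'
#' @param cases Data frame of SGA subjects with columns `subject_id`,
#'   `sex`, `maternal_age`, `gestational_age`.
#' @param pool Data frame of candidate non-SGA controls, same columns.
#' @param age_window Maternal age window in years (default 3).
#' @param ga_window Gestational age window in days (default 2).
#' @return A tibble with one row per case: `case_id`, `control_id` (`NA`
#'   if unmatched), `age_diff`, `ga_diff`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 200, seed = 4))
#' cases <- dplyr::filter(cohort, growth_category == "SGA")
#' pool <- dplyr::filter(cohort, growth_category != "SGA")
#' match_controls(cases, pool)
#' @export
match_controls <- function(cases, pool, age_window = 3, ga_window = 2) {
  if (nrow(cases) == 0) {
    return(tibble(case_id = character(), control_id = character(),
                  age_diff = numeric(), ga_diff = numeric()))
  }
  cases <- dplyr::arrange(as_tibble(cases), .data$subject_id)
  pool <- as_tibble(pool)
  used <- character(0)
  rows <- purrr::map(seq_len(nrow(cases)), function(i) {
    ca <- cases[i, ]
    cand <- dplyr::filter(pool,
                          .data$sex == ca$sex,
                          abs(.data$maternal_age - ca$maternal_age) <= age_window,
                          abs(.data$gestational_age - ca$gestational_age) <= ga_window,
                          !(.data$subject_id %in% used),
                          .data$subject_id != ca$subject_id)
    if (nrow(cand) == 0) {
      return(tibble(case_id = ca$subject_id, control_id = NA_character_,
                    age_diff = NA_real_, ga_diff = NA_real_))
    }
    cand <- dplyr::mutate(cand,
                          age_diff = abs(.data$maternal_age - ca$maternal_age),
                          ga_diff = abs(.data$gestational_age - ca$gestational_age))
    cand <- dplyr::arrange(cand, .data$age_diff, .data$ga_diff,
                           .data$subject_id)
    used <<- c(used, cand$subject_id[1])
    tibble(case_id = ca$subject_id, control_id = cand$subject_id[1],
           age_diff = cand$age_diff[1], ga_diff = cand$ga_diff[1])
  })
  dplyr::bind_rows(rows)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on
#' `groups - 1` degrees of freedom, as used for continuous covariates
#' across birth-weight groups. Wraps [stats::kruskal.test()].
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (coerced to factor), at least two levels
#'   present.
#' @return A tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) {
    abort("kruskal_wallis requires at least two groups")
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(values))
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square without continuity correction on a two-way count
#' table, `(r - 1)(c - 1)` degrees of freedom. All expected counts must be
#' positive. Wraps [stats::chisq.test()].
#'
#' @param table A matrix (or table) of counts.
#' @return A tibble: `statistic`, `df`, `p_value`, `n`.
#' @examples
#' chi_square(matrix(c(20, 10, 10, 20), 2))
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(!is.finite(tab))) abort("counts must be nonnegative")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) {
    abort("all expected counts must be positive (empty row or column?)")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, n = sum(tab))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length, n >= 4, non-constant.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `r`, `conf_low`, `conf_high`, `n`.
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 1))
#' pearson_ci(cohort$line1, cohort$aluyb8)
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  r <- cor(x, y)
  z <- atanh(r)
  half <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  tibble(r = r, conf_low = tanh(z - half), conf_high = tanh(z + half), n = n)
}

#' Adjusted birth-weight-percentile regression for a repeat marker
#'
#' Ordinary least squares of birth weight percentile on one repeat-element
#' methylation marker — rescaled so the coefficient is per 10
#' percentage-point methylation increase — adjusted for infant sex (female
#' referent), maternal age, pre-pregnancy BMI, ethnicity (non-Caucasian
#' referent), and tobacco, alcohol and prenatal vitamin use. Complete-case
#' analysis.
#'
#' @param cohort Cohort tibble as produced by [simulate_cohort()] (or read
#'   with [read_cohort()]).
#' @param marker `"line1"` or `"aluyb8"`.
#' @param conf_level Confidence level for the reported intervals.
#' @return An object of class `"bw_model"` wrapping the [stats::lm()] fit;
#'   use [tidy()] for the coefficient table (marker row labelled
#'   `"<marker> (per 10%)"`) and [glance()] for model-level summaries.
#' @examples
#' fit <- fit_birthweight_model(simulate_cohort(sim_config(seed = 1)),
#'                              "line1")
#' tidy(fit)
#' @export
fit_birthweight_model <- function(cohort, marker = c("line1", "aluyb8"),
                                  conf_level = 0.95) {
  marker <- match.arg(marker)
  cohort <- as_tibble(cohort)
  needed <- c("birthweight_percentile", marker, "sex", "maternal_age",
              "bmi", "ethnicity", "tobacco", "alcohol", "vitamins")
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) {
    abort(paste("cohort is missing columns:", paste(miss, collapse = ", ")))
  }
  dat <- dplyr::transmute(
    cohort,
    birthweight_percentile = .data$birthweight_percentile,
    marker_per10 = .data[[marker]] / 10,
    male = as.numeric(.data$sex == "male"),
    maternal_age = .data$maternal_age,
    bmi = .data$bmi,
    caucasian = as.numeric(.data$ethnicity == "Caucasian"),
    tobacco = as.numeric(as.logical(.data$tobacco)),
    alcohol = as.numeric(as.logical(.data$alcohol)),
    vitamins = as.numeric(as.logical(.data$vitamins))
  )
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) < 20) abort("need at least 20 complete cases")

  # constant covariates (e.g. no alcohol users in a small cohort) carry no
  # information and would alias the fit; drop them with a warning
  covars <- c("marker_per10", "male", "maternal_age", "bmi", "caucasian",
              "tobacco", "alcohol", "vitamins")
  constant <- covars[vapply(dat[covars], function(v) var(v) == 0,
                            logical(1))]
  if ("marker_per10" %in% constant) abort("marker is constant")
  if (length(constant)) {
    warn(paste("dropping constant covariate(s):",
               paste(constant, collapse = ", ")))
  }
  form <- stats::reformulate(setdiff(covars, constant),
                             response = "birthweight_percentile")
  fit <- lm(form, data = dat)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(paste("collinear design; aliased terms:",
                paste(names(coef(fit))[aliased], collapse = ", ")))
  }
  structure(list(fit = fit, marker = marker, n = nrow(dat),
                 conf_level = conf_level),
            class = "bw_model")
}

#' @export
print.bw_model <- function(x, ...) {
  td <- tidy(x)
  mk <- td[td$term == paste0(x$marker, " (per 10%)"), ]
  cat(sprintf("<bw_model> %s, n = %d\n", x$marker, x$n))
  cat(sprintf("  %s: %.2f (%.2f, %.2f), p = %.3g\n", mk$term, mk$estimate,
              mk$conf_low, mk$conf_high, mk$p_value))
  invisible(x)
}

#' @describeIn fit_birthweight_model Coefficient table with confidence
#'   intervals, one row per model term.
#' @param x A `bw_model`.
#' @param ... Unused.
#' @method tidy bw_model
#' @export
tidy.bw_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = x$conf_level)
  term <- rownames(sm)
  term[term == "marker_per10"] <- paste0(x$marker, " (per 10%)")
  tibble(term = term,
         estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
         statistic = unname(sm[, 3]), p_value = unname(sm[, 4]),
         conf_low = unname(ci[, 1]), conf_high = unname(ci[, 2]))
}

#' @describeIn fit_birthweight_model One-row model summary (`r_squared`,
#'   `sigma`, `n`, `df_residual`).
#' @method glance bw_model
#' @export
glance.bw_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma, n = x$n,
         df_residual = x$fit$df.residual)
}
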