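#' Configuration for the synthetic cohort and beta-matrix generator
#'
#' Builds the parameter set that drives [simulate_cohort()],
#' [simulate_beta_matrix()] and [simulate_annotation()]. Defaults are
#' calibrated to the descriptive statistics of a term-placenta fetal-growth
#' study: 380 subjects with repeat-element pyrosequencing (LINE-1 mean
#' 51.7%, SD 4.6; AluYb8 mean 65.0%, SD 3.3; Pearson correlation 0.29), a
#' 184-subject array subset, and marginal birth-weight-percentile effects
#' of 9.7 (LINE-1) and 14.5 (AluYb8) percentile points per 10% methylation.
#'
#' @param n_subjects Number of subjects in the pyrosequencing cohort.
#' @param n_array_subjects Number of subjects with array data (a subset).
#' @param n_loci Number of CpG loci in the simulated beta-matrix. The
#'   default 2000 is a desk-scale stand-in for a 26,486-locus autosomal
#'   array; set larger for full-scale runs.
#' @param n_latent_classes Number of latent methylation classes.
#' @param marker_means,marker_sds Length-2 numeric vectors (LINE-1, AluYb8)
#'   of percent-methylation means and SDs.
#' @param marker_correlation Correlation between the two repeat markers.
#' @param effect_line1_per10,effect_alu_per10 Target marginal effect of each
#'   marker on birth weight percentile, per 10 percentage-point methylation
#'   increase, as estimated by a single-marker adjusted regression.
#' @param effect_male_sex,effect_white_ethnicity,effect_tobacco Percentile-
#'   point effects of the binary covariates (referents: female,
#'   non-Caucasian, no tobacco). `effect_tobacco` defaults to 0; set it
#'   negative to induce the tobacco/SGA imbalance seen in observational
#'   cohorts.
#' @param covariate_prevalences Named proportions for the binary covariates:
#'   `male`, `caucasian`, `tobacco`, `alcohol`, `vitamins`.
#' @param residual_sd Residual SD of the birth-weight-percentile regression,
#'   in percentile points.
#' @param baseline_percentile Expected percentile at covariate means.
#' @param maternal_age,bmi,gestational_age Length-2 `c(mean, sd)` vectors for
#'   the continuous covariates (years, kg/m2, days).
#' @param class_means Per-class mean methylation (fraction), strictly
#'   increasing; class 1 is the least methylated.
#' @param class_precision Beta precision (a + b) of each latent class;
#'   recycled to `n_latent_classes`.
#' @param class_props Mixing proportions of the latent classes (sum to 1).
#' @param attribute_frequencies Named marginal probabilities of the locus
#'   attributes: `cgi`, `pcg`, `tfbs`, and repeat overlaps `alu`, `line1`,
#'   `line2`, `mir` (repeat categories are mutually exclusive and must sum
#'   to at most 1).
#' @param n_tfbs_factors Number of distinct transcription-factor binding-site
#'   identities available to annotate TFBS-proximal loci.
#' @param effects_are_marginal If `TRUE` (default) the configured marker
#'   effects are interpreted as the target coefficients of single-marker
#'   fitted models and the generator solves for the structural coefficients
#'   of the joint linear predictor; if `FALSE` they are used structurally.
#' @param seed Default seed used by the generator functions when their
#'   `seed` argument is left `NULL`.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_subjects = 50, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_subjects = 380,
                       n_array_subjects = min(184, n_subjects),
                       n_loci = 2000,
                       n_latent_classes = 16,
                       marker_means = c(line1 = 51.7, aluyb8 = 65.0),
                       marker_sds = c(line1 = 4.6, aluyb8 = 3.3),
                       marker_correlation = 0.29,
                       effect_line1_per10 = 9.7,
                       effect_alu_per10 = 14.5,
                       effect_male_sex = 12.81,
                       effect_white_ethnicity = 7.06,
                       effect_tobacco = 0,
                       covariate_prevalences = c(male = 190 / 380,
                                                 caucasian = 217 / 380,
                                                 tobacco = 36 / 380,
                                                 alcohol = 3 / 380,
                                                 vitamins = 314 / 380),
                       residual_sd = 22,
                       baseline_percentile = 50,
                       maternal_age = c(mean = 29, sd = 5),
                       bmi = c(mean = 26.5, sd = 5.5),
                       gestational_age = c(mean = 276, sd = 8),
                       class_means = NULL,
                       class_precision = 100,
                       class_props = NULL,
                       attribute_frequencies = c(cgi = 0.73, pcg = 0.12,
                                                 tfbs = 0.50, alu = 0.08,
                                                 line1 = 0.05, line2 = 0.04,
                                                 mir = 0.03),
                       n_tfbs_factors = 258,
                       effects_are_marginal = TRUE,
                       seed = NULL) {
  if (is.null(class_means)) {
    class_means <- default_class_means(n_latent_classes)
  }
  if (is.null(class_props)) {
    class_props <- rep(1 / n_latent_classes, n_latent_classes)
  }
  class_precision <- rep_len(class_precision, n_latent_classes)

  cfg <- structure(list(
    n_subjects = n_subjects,
    n_array_subjects = n_array_subjects,
    n_loci = n_loci,
    n_latent_classes = n_latent_classes,
    marker_means = marker_means,
    marker_sds = marker_sds,
    marker_correlation = marker_correlation,
    effect_line1_per10 = effect_line1_per10,
    effect_alu_per10 = effect_alu_per10,
    effect_male_sex = effect_male_sex,
    effect_white_ethnicity = effect_white_ethnicity,
    effect_tobacco = effect_tobacco,
    covariate_prevalences = covariate_prevalences,
    residual_sd = residual_sd,
    baseline_percentile = baseline_percentile,
    maternal_age = maternal_age,
    bmi = bmi,
    gestational_age = gestational_age,
    class_means = class_means,
    class_precision = class_precision,
    class_props = class_props,
    attribute_frequencies = attribute_frequencies,
    n_tfbs_factors = n_tfbs_factors,
    effects_are_marginal = effects_are_marginal,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# Default ladder of latent-class mean methylation fractions. Chosen once so
# that, with equal mixing proportions, the matrix-wide mean (~0.242) sits on
# the genomewide scale of 27K-style arrays and neighbouring classes are
# separated by >= 0.02, supporting depth-4 recovery.
default_class_means <- function(k) {
  base <- c(0.020, 0.045, 0.070, 0.095, 0.120, 0.145, 0.170, 0.195,
            0.220, 0.250, 0.280, 0.320, 0.370, 0.430, 0.520, 0.620)
  if (k == 16L) return(base)
  # other class counts: evenly spaced quantiles of the same ladder
  stats::approx(seq_len(16), base, xout = seq(1, 16, length.out = k))$y
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_subjects, cfg$n_array_subjects, cfg$n_loci,
              cfg$n_latent_classes)
  if (any(counts <= 0) || any(counts != round(counts))) {
    abort("all counts in a sim_config must be positive integers")
  }
  if (cfg$n_array_subjects > cfg$n_subjects) {
    abort("n_array_subjects cannot exceed n_subjects")
  }
  if (abs(cfg$marker_correlation) >= 1) {
    abort("marker_correlation must lie in (-1, 1)")
  }
  if (any(cfg$marker_sds <= 0)) abort("marker_sds must be positive")
  prev <- cfg$covariate_prevalences
  if (any(prev < 0 | prev > 1)) {
    abort("covariate_prevalences must lie in [0, 1]")
  }
  if (cfg$residual_sd <= 0) abort("residual_sd must be positive")
  if (length(cfg$class_means) != cfg$n_latent_classes) {
    abort("class_means must have one entry per latent class")
  }
  if (any(diff(cfg$class_means) <= 0)) {
    abort("class_means must be strictly increasing (class 1 is lowest)")
  }
  if (any(cfg$class_means <= 0 | cfg$class_means >= 1)) {
    abort("class_means must lie strictly inside (0, 1)")
  }
  if (any(cfg$class_precision <= 0)) {
    abort("class_precision implies beta shapes <= 0; must be positive")
  }
  if (abs(sum(cfg$class_props) - 1) > 1e-8 || any(cfg$class_props < 0)) {
    abort("class_props must be nonnegative and sum to 1")
  }
  af <- cfg$attribute_frequencies
  if (any(af < 0 | af > 1)) {
    abort("attribute_frequencies must lie in [0, 1]")
  }
  rep_total <- sum(af[c("alu", "line1", "line2", "mir")], na.rm = TRUE)
  if (rep_total > 1) {
    abort("repeat-category frequencies (alu/line1/line2/mir) must sum to <= 1")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  subjects:", x$n_subjects,
      "(array subset:", paste0(x$n_array_subjects, ")"), "\n")
  cat("  loci:", x$n_loci, "in", x$n_latent_classes, "latent classes\n")
  cat(sprintf("  markers: LINE-1 %.1f%% (SD %.1f), AluYb8 %.1f%% (SD %.1f), r = %.2f\n",
              x$marker_means[1], x$marker_sds[1],
              x$marker_means[2], x$marker_sds[2], x$marker_correlation))
  cat(sprintf("  marginal effects per 10%%: LINE-1 %.1f, AluYb8 %.1f percentile points\n",
              x$effect_line1_per10, x$effect_alu_per10))
  invisible(x)
}
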