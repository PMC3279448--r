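#' Simulate a pyrosequencing cohort
#'
#' Draws a synthetic cohort with the covariate structure the downstream
#' birth-weight analyses assume: binary exposures at configured
#' prevalences, truncated-normal maternal age / BMI / gestational age,
#' a correlated truncated-bivariate-normal pair of repeat-element
#' methylation markers (LINE-1, AluYb8, percent scale), and a birth weight
#' percentile generated from a linear predictor on centred covariates plus
#' Gaussian noise, truncated to (0.1, 99.9).
#'
#' When `config$effects_are_marginal` is `TRUE`, the configured per-10%
#' marker effects are treated as the target coefficients of single-marker
#' adjusted regressions; because the two markers are correlated, the
#' generator solves a 2x2 linear system for the structural coefficients of
#' the joint predictor so that each fitted single-marker model recovers its
#' configured effect in expectation.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. `NULL` leaves the
#'   RNG state untouched.
#' @return A tibble with one row per subject: `subject_id`, `sex`,
#'   `maternal_age`, `bmi`, `ethnicity`, `tobacco`, `alcohol`, `vitamins`,
#'   `gestational_age`, `line1`, `aluyb8`, `birthweight_percentile`,
#'   `growth_category`.
#' @seealso [simulate_beta_matrix()], [simulate_annotation()]
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 100, seed = 7))
#' dplyr::count(cohort, growth_category)
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  prev <- config$covariate_prevalences

  sex <- ifelse(rbinom(n, 1, prev[["male"]]) == 1, "male", "female")
  ethnicity <- ifelse(rbinom(n, 1, prev[["caucasian"]]) == 1,
                      "Caucasian", "non-Caucasian")
  tobacco <- rbinom(n, 1, prev[["tobacco"]]) == 1
  alcohol <- rbinom(n, 1, prev[["alcohol"]]) == 1
  vitamins <- rbinom(n, 1, prev[["vitamins"]]) == 1

  maternal_age <- rtrunc_norm(n, config$maternal_age[["mean"]],
                              config$maternal_age[["sd"]], 18, 40)
  bmi <- rtrunc_norm(n, config$bmi[["mean"]], config$bmi[["sd"]], 16, 45)
  gestational_age <- round(rtrunc_norm(n, config$gestational_age[["mean"]],
                                       config$gestational_age[["sd"]],
                                       260, 294))

  mk <- draw_markers(n, config)
  b <- marker_structural_effects(config)

  lp <- config$baseline_percentile +
    b[["line1"]] * (mk$line1 - config$marker_means[[1]]) +
    b[["aluyb8"]] * (mk$aluyb8 - config$marker_means[[2]]) +
    config$effect_male_sex * ((sex == "male") - prev[["male"]]) +
    config$effect_white_ethnicity *
      ((ethnicity == "Caucasian") - prev[["caucasian"]]) +
    config$effect_tobacco * (tobacco - prev[["tobacco"]])
  pct <- lp + rnorm(n, 0, config$residual_sd)
  pct <- pmin(pmax(pct, 0.1), 99.9)

  tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    maternal_age = maternal_age,
    bmi = bmi,
    ethnicity = ethnicity,
    tobacco = tobacco,
    alcohol = alcohol,
    vitamins = vitamins,
    gestational_age = gestational_age,
    line1 = mk$line1,
    aluyb8 = mk$aluyb8,
    birthweight_percentile = pct,
    growth_category = classify_growth(pct)
  )
}

# truncated normal via inverse-CDF sampling (exact, no rejection loop)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

# correlated marker pair on the percent scale, truncated to [0, 100]
draw_markers <- function(n, config) {
  rho <- config$marker_correlation
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  line1 <- config$marker_means[[1]] + config$marker_sds[[1]] * z1
  aluyb8 <- config$marker_means[[2]] + config$marker_sds[[2]] * z2
  list(line1 = pmin(pmax(line1, 0), 100),
       aluyb8 = pmin(pmax(aluyb8, 0), 100))
}

# Per-unit structural coefficients of the joint linear predictor. With
# effects_are_marginal, solve
#   b_L + b_A * rho * sA/sL = m_L
#   b_A + b_L * rho * sL/sA = m_A
# so single-marker fits recover the configured marginal effects.
marker_structural_effects <- function(config) {
  m <- c(line1 = config$effect_line1_per10 / 10,
         aluyb8 = config$effect_alu_per10 / 10)
  if (!config$effects_are_marginal) return(m)
  rho <- config$marker_correlation
  s <- config$marker_sds
  A <- matrix(c(1, rho * s[[2]] / s[[1]],
                rho * s[[1]] / s[[2]], 1),
              2, 2, byrow = TRUE)
  setNames(as.numeric(solve(A, m)), c("line1", "aluyb8"))
}

#' Simulate a latent-class beta-value matrix
#'
#' Assigns each CpG locus to one of `n_latent_classes` latent methylation
#' classes (multinomial at the configured mixing proportions) and draws its
#' per-subject beta-values from the class beta distribution
#' `Beta(mu * s, (1 - mu) * s)` with class mean `mu` and precision `s`.
#' Class means are strictly increasing, so class 1 is the least methylated.
#'
#' @inheritParams simulate_cohort
#' @param n_subjects Number of subject columns; defaults to
#'   `config$n_array_subjects`.
#' @return A list of class `"beta_sim"` with elements `beta` (numeric
#'   matrix, loci x subjects, dimnames set), `truth` (tibble `locus_id`,
#'   `latent_class`) and `class_params` (tibble `class`, `mean`,
#'   `precision`, `prop`).
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 200, seed = 1),
#'                             n_subjects = 20)
#' dim(sim$beta)
#' @export
simulate_beta_matrix <- function(config = sim_config(),
                                 n_subjects = config$n_array_subjects,
                                 seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_loci <- config$n_loci
  k <- config$n_latent_classes

  latent <- sample.int(k, n_loci, replace = TRUE, prob = config$class_props)
  a <- config$class_means * config$class_precision
  b <- (1 - config$class_means) * config$class_precision
  if (any(a <= 0) || any(b <= 0)) abort("class beta shapes must be positive")

  beta <- matrix(rbeta(n_loci * n_subjects, a[latent], b[latent]),
                 nrow = n_loci, ncol = n_subjects)
  dimnames(beta) <- list(sprintf("cg%05d", seq_len(n_loci)),
                         sprintf("S%04d", seq_len(n_subjects)))

  structure(list(
    beta = beta,
    truth = tibble(locus_id = rownames(beta), latent_class = latent),
    class_params = tibble(class = seq_len(k),
                          mean = config$class_means,
                          precision = config$class_precision,
                          prop = config$class_props)
  ), class = "beta_sim")
}

#' Simulate a locus annotation table
#'
#' Draws per-locus genomic attributes: chromosome, CpG-island (CGI) status,
#' polycomb-group (PcG) target status, proximity (within 1 kb) to at least
#' one predicted transcription-factor binding site (TFBS), a mutually
#' exclusive repeat-element overlap (Alu / LINE-1 / LINE-2 / MIR / none),
#' and — for TFBS-proximal loci — the set of named factors with a site
#' nearby, drawn from `n_tfbs_factors` identities with a long-tailed
#' popularity profile so that factor set sizes vary.
#'
#' @inheritParams simulate_cohort
#' @param labels Optional integer vector of per-locus latent classes (as in
#'   `simulate_beta_matrix()$truth$latent_class`); required when
#'   `class_overrides` is supplied.
#' @param class_overrides Optional named list making attribute
#'   probabilities class-dependent, e.g.
#'   `list(cgi = c("9" = 0.81), pcg = c("9" = 0.32))`: for attribute `cgi`,
#'   loci in latent class 9 use probability 0.81 instead of the marginal.
#' @param chromosomes Chromosome names to sample uniformly; defaults to the
#'   22 autosomes (the matrix generator emulates a post-filter autosomal
#'   array).
#' @return A tibble with columns `locus_id`, `chromosome`, `cgi`,
#'   `pcg_target`, `tfbs`, `rep_alu`, `rep_line1`, `rep_line2`, `rep_mir`,
#'   and list-column `tfbs_factors` (character vector per locus, empty
#'   unless `tfbs` is `TRUE`).
#' @examples
#' ann <- simulate_annotation(sim_config(n_loci = 100, seed = 2))
#' mean(ann$cgi)
#' @export
simulate_annotation <- function(config = sim_config(),
                                labels = NULL,
                                class_overrides = NULL,
                                chromosomes = as.character(1:22),
                                seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_loci
  af <- config$attribute_frequencies
  if (!is.null(class_overrides) && is.null(labels)) {
    abort("class_overrides requires per-locus latent-class labels")
  }
  if (!is.null(labels) && length(labels) != n) {
    abort("labels must have one latent class per locus")
  }

  attr_prob <- function(name) {
    p <- rep(af[[name]], n)
    ov <- class_overrides[[name]]
    if (!is.null(ov)) {
      for (cls in names(ov)) p[labels == as.integer(cls)] <- ov[[cls]]
    }
    p
  }

  cgi <- runif(n) < attr_prob("cgi")
  pcg <- runif(n) < attr_prob("pcg")
  tfbs <- runif(n) < attr_prob("tfbs")

  rep_p <- af[c("alu", "line1", "line2", "mir")]
  rep_cat <- apply(stats::rmultinom(n, 1,
                                    c(rep_p, none = 1 - sum(rep_p))) == 1,
                   2, which)
  rep_names <- c("alu", "line1", "line2", "mir", "none")[rep_cat]

  factor_names <- sprintf("TF%03d", seq_len(config$n_tfbs_factors))
  pop <- seq_len(config$n_tfbs_factors)^-0.7  # long-tailed popularity
  tfbs_factors <- vector("list", n)
  n_hits <- ifelse(tfbs, 1L + stats::rpois(n, 2), 0L)
  for (i in which(n_hits > 0L)) {
    tfbs_factors[[i]] <- sort(sample(factor_names,
                                     min(n_hits[i], length(factor_names)),
                                     prob = pop))
  }
  tfbs_factors[n_hits == 0L] <- list(character(0))

  tibble(
    locus_id = sprintf("cg%05d", seq_len(n)),
    chromosome = sample(chromosomes, n, replace = TRUE),
    cgi = cgi,
    pcg_target = pcg,
    tfbs = tfbs,
    rep_alu = rep_names == "alu",
    rep_line1 = rep_names == "line1",
    rep_line2 = rep_names == "line2",
    rep_mir = rep_names == "mir",
    tfbs_factors = tfbs_factors
  )
}
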