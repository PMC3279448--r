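#' Beta-value from methylated/unmethylated intensities
#'
#' Computes the methylation fraction from average probe intensities for the
#' methylated (M) and unmethylated (U) alleles:
#' `beta = max(M, 0) / (max(M, 0) + max(U, 0) + 100)`. Negative intensities
#' are clamped to zero before the ratio; the +100 offset stabilises
#' low-intensity loci, so the result is always strictly below 1.
#'
#' @param M,U Numeric vectors of methylated / unmethylated intensities
#'   (arbitrary fluorescence units; recycled to a common length).
#' @return Numeric vector of beta fractions in `[0, 1)`.
#' @examples
#' beta_from_intensities(900, 0)   # 0.9
#' beta_from_intensities(-50, 100) # 0
#' @export
beta_from_intensities <- function(M, U) {
  if (!is.numeric(M) || !is.numeric(U) || any(!is.finite(M)) ||
      any(!is.finite(U))) {
    abort("intensities must be finite numerics")
  }
  m <- pmax(M, 0)
  u <- pmax(U, 0)
  m / (m + u + 100)
}

# per-element CpG position counts of the pyrosequencing assays
.repeat_positions <- c("LINE-1" = 4L, "AluYb8" = 5L)

#' Summarise a repeat-element pyrosequencing measurement
#'
#' The methylation extent of a repeat element is the arithmetic mean of its
#' assayed CpG positions: 4 positions for LINE-1, 5 for AluYb8, on the
#' 0-100 percent scale.
#'
#' @param element `"LINE-1"` or `"AluYb8"`.
#' @param position_values Numeric vector of per-position percent
#'   methylation; its length must match the element's assay.
#' @return Mean percent methylation (scalar).
#' @examples
#' mean_repeat_methylation("LINE-1", c(51, 52, 51, 52))
#' @export
mean_repeat_methylation <- function(element, position_values) {
  element <- match.arg(element, names(.repeat_positions))
  expected <- .repeat_positions[[element]]
  if (length(position_values) != expected) {
    abort(sprintf("%s requires exactly %d position values, got %d",
                  element, expected, length(position_values)))
  }
  if (any(!is.finite(position_values)) ||
      any(position_values < 0 | position_values > 100)) {
    abort("position values must be percentages in [0, 100]")
  }
  mean(position_values)
}

#' Mahalanobis outlier screen of array samples
#'
#' Summarises each subject column of a beta-matrix by a low-dimensional
#' vector — mean beta, SD of beta, and the fraction of loci with beta >
#' 0.7 — and computes each subject's squared Mahalanobis distance to the
#' cohort mean under the cohort covariance. Subjects beyond the
#' `chi-square(p)` upper-`alpha` quantile are flagged.
#'
#' @param beta Numeric matrix, loci x subjects, values in `[0, 1]`.
#' @param alpha Upper tail probability for the flag threshold (default
#'   0.001).
#' @param summary_fn Optional function mapping a subject's beta vector to a
#'   numeric summary vector; the default is the 3-dimensional summary
#'   above, which keeps the covariance well-conditioned at modest n.
#' @return A tibble of class `"outlier_report"`: `subject_id`, `distance`
#'   (squared Mahalanobis), `flagged`, with the threshold and `alpha`
#'   stored as attributes.
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 300, seed = 3),
#'                             n_subjects = 30)
#' screen_outliers(sim$beta)
#' @export
screen_outliers <- function(beta, alpha = 0.001, summary_fn = NULL) {
  check_beta_matrix(beta)
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (is.null(summary_fn)) {
    summary_fn <- function(x) c(mean = mean(x), sd = sd(x),
                                frac_high = mean(x > 0.7))
  }
  S <- t(apply(beta, 2, summary_fn))
  p <- ncol(S)
  if (nrow(S) < p + 2) {
    abort(sprintf("need at least %d subjects for a %d-dimensional screen",
                  p + 2, p))
  }
  center <- colMeans(S)
  covm <- stats::cov(S)
  if (!is.finite(rcond_sym(covm)) || rcond_sym(covm) < 1e-12) {
    abort(paste("summary covariance is (near-)singular; reduce the",
                "summary dimension or drop constant features"))
  }
  d2 <- mahalanobis(S, center, covm)
  # alpha = 1 is read as "screen disabled": infinite threshold, no flags
  threshold <- if (alpha >= 1) Inf else qchisq(1 - alpha, df = p)
  out <- tibble(subject_id = colnames(beta) %||% sprintf("S%04d", seq_len(nrow(S))),
                distance = as.numeric(d2),
                flagged = as.numeric(d2) > threshold)
  structure(out, threshold = threshold, alpha = alpha, df = p,
            class = c("outlier_report", class(out)))
}

rcond_sym <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || any(ev <= 0)) return(0)
  min(ev) / max(ev)
}

#' Restrict a beta-matrix to autosomal loci
#'
#' Removes loci whose annotated chromosome is X or Y, preserving the order
#' of the remaining rows. Sex-chromosome loci are excluded from downstream
#' clustering to avoid sex-specific methylation bias.
#'
#' @param beta Numeric matrix, loci x subjects, with locus IDs as rownames.
#' @param annotation Data frame with columns `locus_id` and `chromosome`
#'   (chromosome labels may be `"X"`, `"chrX"`, etc.).
#' @return The filtered beta matrix.
#' @examples
#' ann <- tibble::tibble(locus_id = c("a", "b"), chromosome = c("1", "X"))
#' m <- matrix(0.5, 2, 3, dimnames = list(c("a", "b"), NULL))
#' nrow(filter_autosomal(m, ann))  # 1
#' @export
filter_autosomal <- function(beta, annotation) {
  check_beta_matrix(beta)
  if (is.null(rownames(beta))) abort("beta matrix must have locus rownames")
  idx <- match(rownames(beta), annotation$locus_id)
  if (anyNA(idx)) {
    missing <- rownames(beta)[is.na(idx)]
    abort(sprintf("loci missing from annotation: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) sprintf(" (and %d more)",
                                                   length(missing) - 5) else ""))
  }
  chrom <- sub("^chr", "", as.character(annotation$chromosome[idx]),
               ignore.case = TRUE)
  keep <- !(toupper(chrom) %in% c("X", "Y"))
  beta[keep, , drop = FALSE]
}

check_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort("beta must be a numeric matrix (loci x subjects)")
  }
  if (anyNA(beta) || any(beta < 0 | beta > 1)) {
    abort("beta values must be non-missing and lie in [0, 1]")
  }
  invisible(beta)
}
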