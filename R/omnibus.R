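# Per-class marker regressions and the max-|t| permutation omnibus test.
#
# Simple regressions of each class's aggregate methylation on a repeat
# marker reduce to correlations: t = r * sqrt(n - 2) / sqrt(1 - r^2) and
# slope = r * sd(y) / sd(x), which lets the permutation null be computed
# with one correlation matrix per block of permutations.

.t_cap <- 1e8

cor_to_t <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  pmin(pmax(t, -.t_cap), .t_cap)
}

#' Per-class regressions of aggregate methylation on a repeat marker
#'
#' For each methylation class, fits the simple least-squares regression of
#' the class's per-subject aggregate beta-value (outcome) on the
#' repeat-element marker (predictor, rescaled to per-10% methylation) and
#' reports the slope and the t-statistic of the marker coefficient.
#' Constant aggregate columns yield t = 0 with a warning; a perfect linear
#' relationship is capped at |t| = 1e8.
#'
#' @param aggregates Class-aggregate tibble from
#'   [aggregate_class_methylation()] (column `subject_id` plus one column
#'   per class).
#' @param marker Numeric vector of per-subject marker percent methylation,
#'   aligned with the aggregate rows (or named by subject ID).
#' @return A tibble: `class`, `slope` (beta fraction per 10% marker
#'   methylation), `t`, `n`.
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 200, seed = 1),
#'                             n_subjects = 30)
#' agg <- aggregate_class_methylation(sim$beta, sim$truth |>
#'   dplyr::rename(class = latent_class))
#' class_regressions(agg, runif(30, 40, 60))
#' @export
class_regressions <- function(aggregates, marker) {
  Y <- aggregate_matrix(aggregates)
  marker <- align_marker(marker, rownames(Y))
  n <- nrow(Y)
  if (n < 10) abort("need at least 10 subjects for class regressions")
  x <- marker / 10  # per-10% scale
  sy <- unname(apply(Y, 2, sd))
  if (sd(x) == 0) abort("marker is constant across subjects")
  if (any(sy == 0)) {
    warn(paste("constant aggregate column(s), t set to 0:",
               paste(colnames(Y)[sy == 0], collapse = ", ")))
  }
  r <- suppressWarnings(as.numeric(cor(x, Y)))
  r[!is.finite(r)] <- 0
  tibble(class = colnames(Y),
         slope = ifelse(sy == 0, 0, r * sy / sd(x)),
         t = ifelse(sy == 0, 0, cor_to_t(r, n)),
         n = n)
}

aggregate_matrix <- function(aggregates) {
  if (!is.data.frame(aggregates) || !"subject_id" %in% names(aggregates)) {
    abort("aggregates must contain a subject_id column (see aggregate_class_methylation)")
  }
  Y <- as.matrix(as.data.frame(
    aggregates[setdiff(names(aggregates), "subject_id")]))
  rownames(Y) <- aggregates$subject_id
  storage.mode(Y) <- "double"
  Y
}

align_marker <- function(marker, subject_ids) {
  if (!is.null(names(marker))) {
    m <- marker[subject_ids]
    if (anyNA(m)) abort("marker is missing values for some subjects")
    return(as.numeric(m))
  }
  if (length(marker) != length(subject_ids)) {
    abort("marker length must match the number of subjects")
  }
  as.numeric(marker)
}

#' Max-|t| permutation omnibus test
#'
#' Tests the overall association between a repeat-element methylation
#' marker and the per-class aggregate methylation values. The observed
#' statistic is the maximum over classes of the absolute regression
#' t-statistic. The null distribution is built by shuffling the marker
#' across subjects (one shared shuffle per replicate, jointly over all
#' class regressions) and recomputing the max |t|; the reported p-value
#' uses the add-one estimator `(1 + #{null >= observed}) / (B + 1)`. The
#' 0.95 quantile of the null max |t| is returned as a symmetric per-class
#' null limit, so individual classes whose |t| exceeds it are significant
#' with family-wise multiplicity control.
#'
#' @inheritParams class_regressions
#' @param B Number of permutations (>= 100; the reference analysis used
#'   10,000).
#' @param seed Integer seed for the permutation stream (`NULL` leaves the
#'   RNG state untouched).
#' @param level Family-wise level of the null limit (default 0.05).
#' @return An object of class `"omnibus_test"`: per-class results (tibble
#'   `class`, `slope`, `t`, `significant`), `max_t` (observed max |t|),
#'   `p_value`, `null_limit`, `null_max_t` (the B permuted maxima), `B`,
#'   `level`, `seed`.
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 200, seed = 1),
#'                             n_subjects = 30)
#' agg <- aggregate_class_methylation(sim$beta, sim$truth |>
#'   dplyr::rename(class = latent_class))
#' ot <- max_t_permutation(agg, runif(30, 40, 60), B = 200, seed = 1)
#' glance(ot)
#' @export
max_t_permutation <- function(aggregates, marker, B = 10000, seed = NULL,
                              level = 0.05) {
  if (B < 100) abort("B must be at least 100 (unstable null below that)")
  obs <- class_regressions(aggregates, marker)
  Y <- aggregate_matrix(aggregates)
  x <- align_marker(marker, rownames(Y)) / 10
  n <- nrow(Y)
  if (!is.null(seed)) set.seed(seed)

  # shared shuffle per replicate across all classes; blocks keep memory flat
  keep <- apply(Y, 2, sd) > 0
  Yk <- Y[, keep, drop = FALSE]
  null_max_r <- numeric(B)
  block <- 500L
  done <- 0L
  while (done < B) {
    nb <- min(block, B - done)
    P <- vapply(seq_len(nb), function(i) x[sample.int(n)], numeric(n))
    R <- suppressWarnings(cor(P, Yk))
    R[!is.finite(R)] <- 0
    null_max_r[done + seq_len(nb)] <- apply(abs(R), 1, max)
    done <- done + nb
  }
  null_max_t <- abs(cor_to_t(null_max_r, n))

  max_t <- max(abs(obs$t))
  p <- (1 + sum(null_max_t >= max_t)) / (B + 1)
  null_limit <- unname(quantile(null_max_t, 1 - level, type = 7))

  per_class <- dplyr::mutate(obs, significant = abs(.data$t) > null_limit)
  structure(list(per_class = per_class, max_t = max_t, p_value = p,
                 null_limit = null_limit, null_max_t = null_max_t,
                 B = B, level = level, seed = seed),
            class = "omnibus_test")
}

#' @export
print.omnibus_test <- function(x, ...) {
  cat(sprintf("<omnibus_test> max |t| = %.3f over %d classes\n",
              x$max_t, nrow(x$per_class)))
  cat(sprintf("  permutation p = %.4g (B = %d), null limit (level %.2f) = %.3f\n",
              x$p_value, x$B, x$level, x$null_limit))
  sig <- x$per_class$class[x$per_class$significant]
  cat("  significant classes:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @describeIn max_t_permutation Per-class results table.
#' @param x An `omnibus_test`.
#' @param ... Unused.
#' @method tidy omnibus_test
#' @export
tidy.omnibus_test <- function(x, ...) x$per_class

#' @describeIn max_t_permutation One-row test summary.
#' @method glance omnibus_test
#' @export
glance.omnibus_test <- function(x, ...) {
  tibble(max_t = x$max_t, p_value = x$p_value, null_limit = x$null_limit,
         B = x$B, level = x$level, n_classes = nrow(x$per_class))
}

#' @describeIn max_t_permutation Dot plot of per-class t-statistics with
#'   symmetric dashed null limits, colour-graded by each class's mean
#'   aggregate methylation when `aggregates` is supplied.
#' @param object An `omnibus_test`.
#' @param aggregates Optional class-aggregate tibble used to colour points
#'   by mean class methylation.
#' @method autoplot omnibus_test
#' @export
autoplot.omnibus_test <- function(object, aggregates = NULL, ...) {
  dat <- object$per_class
  dat$class <- factor(dat$class, levels = dat$class)
  if (!is.null(aggregates)) {
    Y <- aggregate_matrix(aggregates)
    dat$mean_methylation <- colMeans(Y)[as.character(dat$class)]
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$null_limit,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "methylation class", y = "t-statistic",
                  title = sprintf("Omnibus max-|t| permutation test (p = %.3g)",
                                  object$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(aggregates)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$mean_methylation),
                            size = 3) +
      ggplot2::scale_colour_viridis_c(name = "mean class\nmethylation")
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}
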