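# Readers and writers for the pipeline's plain-text interchange formats:
# TSV for matrices, CSV for tables, JSON for truth/summaries.

#' Read a beta-value matrix from TSV
#'
#' Expects loci as rows with a `locus_id` first column and one numeric
#' column per subject. Values must lie in `[0, 1]`; out-of-range or
#' non-numeric cells and duplicated locus IDs are errors, not clamped.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, loci x subjects, with dimnames.
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "locus_id") {
    abort("first column of a beta-matrix TSV must be locus_id")
  }
  ids <- as.character(df$locus_id)
  if (anyDuplicated(ids)) {
    abort(paste("duplicated locus IDs:",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(m) | !is.finite(m), arr.ind = TRUE)
    abort(sprintf("non-numeric or missing beta at locus %s, subject %s",
                  ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  out_of_range <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    abort(sprintf("beta value %.4g outside [0, 1] at locus %s, subject %s",
                  m[out_of_range[1, , drop = FALSE]],
                  ids[out_of_range[1, 1]],
                  colnames(m)[out_of_range[1, 2]]))
  }
  rownames(m) <- ids
  m
}

#' @rdname read_beta_matrix
#' @param beta Numeric matrix to write.
#' @export
write_beta_matrix <- function(beta, path) {
  check_beta_matrix(beta)
  df <- dplyr::bind_cols(
    tibble(locus_id = rownames(beta) %||% sprintf("L%05d", seq_len(nrow(beta)))),
    as_tibble(beta, .name_repair = "minimal"))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a cohort table (CSV)
#'
#' @param path Path to a CSV file with the column layout produced by
#'   [simulate_cohort()].
#' @return A cohort tibble; `growth_category` is re-derived from
#'   `birthweight_percentile` on read so the invariant between the two
#'   always holds.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$growth_category <- classify_growth(df$birthweight_percentile)
  as_tibble(df)
}

#' @rdname read_cohort
#' @param cohort Cohort tibble to write.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read / write a locus annotation table (TSV)
#'
#' The list-column of TFBS factor identities is serialised as a
#' comma-joined string (empty for loci with no nearby site) and restored
#' on read.
#'
#' @param path Path to a TSV file.
#' @return Annotation tibble (see [simulate_annotation()]).
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          chromosome = readr::col_character(),
                          tfbs_factors = readr::col_character()))
  df$tfbs_factors <- purrr::map(df$tfbs_factors, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
  as_tibble(df)
}

#' @rdname read_annotation
#' @param annotation Annotation tibble to write.
#' @export
write_annotation <- function(annotation, path) {
  out <- annotation
  out$tfbs_factors <- vapply(annotation$tfbs_factors, paste,
                             character(1), collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic data bundle to a directory
#'
#' Generates a linked cohort, beta-matrix, annotation and ground-truth
#' record from one configuration and writes them as `cohort.csv`,
#' `beta.tsv`, `annotation.tsv` and `truth.json`. The files round-trip
#' through the package readers unchanged.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; stage seeds are derived from it.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
write_synthetic_bundle <- function(config = sim_config(), outdir,
                                   seed = config$seed %||% 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config, seed = seed)
  sim <- simulate_beta_matrix(config, seed = seed + 1L)
  annotation <- simulate_annotation(config, labels = sim$truth$latent_class,
                                    seed = seed + 2L)
  paths <- list(cohort = file.path(outdir, "cohort.csv"),
                beta = file.path(outdir, "beta.tsv"),
                annotation = file.path(outdir, "annotation.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_cohort(cohort, paths$cohort)
  write_beta_matrix(sim$beta, paths$beta)
  write_annotation(annotation, paths$annotation)
  jsonlite::write_json(
    list(seed = seed,
         latent_class = setNames(as.list(sim$truth$latent_class),
                                 sim$truth$locus_id),
         class_params = sim$class_params,
         effects = list(line1_per10 = config$effect_line1_per10,
                        alu_per10 = config$effect_alu_per10,
                        male_sex = config$effect_male_sex,
                        white_ethnicity = config$effect_white_ethnicity)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, beta = sim$beta, truth = sim$truth,
                 annotation = annotation, paths = paths))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their analysis order on a synthetic bundle (or
#' on supplied inputs): outlier screen and autosomal filter, cohort
#' univariate statistics and adjusted birth-weight regressions for both
#' markers, RPMM clustering, bioinformatic classing, per-subject class
#' aggregation, the max-|t| permutation omnibus for every marker x scheme
#' combination, and TFBS GSEA per marker. A markdown report and CSV/TSV
#' artifacts are written when `outdir` is given; every artifact records
#' the seed and a configuration hash.
#'
#' @param config A [sim_config()] used to generate any input not supplied.
#' @param cohort,beta,annotation Optional pre-built inputs (tibble, matrix,
#'   tibble); when `NULL` they are simulated from `config`.
#' @param outdir Optional output directory for artifacts and `report.md`.
#' @param B Number of permutations for the omnibus and GSEA stages.
#' @param gsea_B Permutations for GSEA (defaults to `B`).
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param max_depth RPMM tree depth.
#' @param drop_outliers Remove subjects flagged by the Mahalanobis screen
#'   before clustering (default TRUE).
#' @param alpha Outlier-screen tail probability.
#' @return A list of class `"betaclass_pipeline"` with elements `cohort`,
#'   `cohort_stats`, `bw_models`, `outliers`, `rpmm`, `bio_classes`,
#'   `aggregates`, `omnibus`, `gsea`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL, beta = NULL,
                         annotation = NULL, outdir = NULL, B = 1000,
                         gsea_B = B, seed = config$seed %||% 1L,
                         max_depth = 4, drop_outliers = TRUE,
                         alpha = 0.001) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  cfg_hash <- rlang::hash(list(config = unclass(config), B = B,
                               seed = seed, max_depth = max_depth))

  truth <- NULL
  if (is.null(cohort)) {
    cohort <- stage("simulate_cohort", simulate_cohort(config, seed = seed))
  }
  if (is.null(beta)) {
    sim <- stage("simulate_beta_matrix",
                 simulate_beta_matrix(config, seed = seed + 1L))
    beta <- sim$beta
    truth <- sim$truth
  }
  if (is.null(annotation)) {
    labels <- if (!is.null(truth)) truth$latent_class else NULL
    annotation <- stage("simulate_annotation",
                        simulate_annotation(config, labels = labels,
                                            seed = seed + 2L))
  }

  # preprocess: autosomal filter then sample outlier screen
  beta <- stage("filter_autosomal", filter_autosomal(beta, annotation))
  outliers <- stage("screen_outliers", screen_outliers(beta, alpha = alpha))
  if (drop_outliers && any(outliers$flagged)) {
    beta <- beta[, !outliers$flagged, drop = FALSE]
  }

  # cohort statistics: marker correlation + adjusted regressions
  cohort_stats <- stage("cohort_stats", list(
    marker_correlation = pearson_ci(cohort$line1, cohort$aluyb8),
    growth_counts = dplyr::count(cohort, .data$growth_category)
  ))
  bw_models <- stage("birthweight_models", list(
    line1 = fit_birthweight_model(cohort, "line1"),
    aluyb8 = fit_birthweight_model(cohort, "aluyb8")
  ))

  # subject alignment between cohort and array subset, by ID intersection
  shared <- intersect(cohort$subject_id, colnames(beta))
  if (length(shared) < ncol(beta)) {
    warn(sprintf("dropping %d array subjects absent from the cohort",
                 ncol(beta) - length(shared)))
  }
  beta_sub <- beta[, shared, drop = FALSE]
  cohort_sub <- cohort[match(shared, cohort$subject_id), ]

  rpmm <- stage("rpmm", rpmm_fit(beta_sub, max_depth = max_depth))
  bio <- stage("bio_classes",
               assign_bioinformatic_classes(
                 annotation[annotation$locus_id %in% rownames(beta_sub), ]))

  aggregates <- stage("aggregate", list(
    rpmm = aggregate_class_methylation(beta_sub, rpmm$assignment),
    bioinformatic = aggregate_class_methylation(beta_sub, bio$assignment)
  ))

  markers <- c("line1", "aluyb8")
  omnibus <- stage("omnibus", {
    out <- list()
    sd_seed <- seed + 10L
    for (scheme in names(aggregates)) {
      for (mk in markers) {
        out[[paste(scheme, mk, sep = "_")]] <-
          max_t_permutation(aggregates[[scheme]], cohort_sub[[mk]],
                            B = B, seed = sd_seed)
        sd_seed <- sd_seed + 1L
      }
    }
    out
  })

  gsea <- stage("gsea", {
    sets <- tfbs_sets(annotation[annotation$locus_id %in% rownames(beta_sub), ])
    if (length(sets) == 0) {
      NULL
    } else {
      setNames(lapply(seq_along(markers), function(i) {
        gsea_permutation(beta_sub, cohort_sub[[markers[i]]], sets,
                         B = gsea_B, seed = seed + 20L + i)
      }), markers)
    }
  })

  result <- structure(list(cohort = cohort, cohort_stats = cohort_stats,
                           bw_models = bw_models, outliers = outliers,
                           rpmm = rpmm, bio_classes = bio,
                           aggregates = aggregates, omnibus = omnibus,
                           gsea = gsea, seed = seed,
                           config_hash = cfg_hash),
                      class = "betaclass_pipeline")
  if (!is.null(outdir)) write_pipeline_artifacts(result, outdir)
  result
}

write_pipeline_artifacts <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(result$bw_models$line1),
                   file.path(outdir, "bw_model_line1.csv"), progress = FALSE)
  readr::write_csv(tidy(result$bw_models$aluyb8),
                   file.path(outdir, "bw_model_aluyb8.csv"), progress = FALSE)
  readr::write_tsv(result$rpmm$assignment,
                   file.path(outdir, "rpmm_assignment.tsv"), progress = FALSE)
  readr::write_csv(result$rpmm$class_summary,
                   file.path(outdir, "rpmm_classes.csv"), progress = FALSE)
  readr::write_csv(result$bio_classes$census,
                   file.path(outdir, "bio_class_census.csv"), progress = FALSE)
  for (nm in names(result$omnibus)) {
    readr::write_csv(tidy(result$omnibus[[nm]]),
                     file.path(outdir, paste0("omnibus_", nm, ".csv")),
                     progress = FALSE)
  }
  jsonlite::write_json(
    c(list(seed = result$seed, config_hash = result$config_hash),
      lapply(result$omnibus, function(o) as.list(glance(o)))),
    file.path(outdir, "omnibus_summary.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$gsea)) {
    for (nm in names(result$gsea)) {
      readr::write_csv(tidy(result$gsea[[nm]]),
                       file.path(outdir, paste0("gsea_", nm, ".csv")),
                       progress = FALSE)
    }
  }
  writeLines(pipeline_report(result), file.path(outdir, "report.md"))
  invisible(outdir)
}

pipeline_report <- function(result) {
  li <- tidy(result$bw_models$line1)
  al <- tidy(result$bw_models$aluyb8)
  mk_row <- function(td, term) td[td$term == term, ]
  l1 <- mk_row(li, "line1 (per 10%)")
  a1 <- mk_row(al, "aluyb8 (per 10%)")
  corr <- result$cohort_stats$marker_correlation
  c(sprintf("# betaclass pipeline report (seed %s, config %s)",
            result$seed, result$config_hash),
    "",
    "## Cohort",
    sprintf("- n = %d subjects; LINE-1/AluYb8 correlation r = %.3f (%.3f, %.3f)",
            nrow(result$cohort), corr$r, corr$conf_low, corr$conf_high),
    sprintf("- LINE-1 per-10%%: %.2f (%.2f, %.2f), p = %.3g",
            l1$estimate, l1$conf_low, l1$conf_high, l1$p_value),
    sprintf("- AluYb8 per-10%%: %.2f (%.2f, %.2f), p = %.3g",
            a1$estimate, a1$conf_low, a1$conf_high, a1$p_value),
    "",
    "## Clustering",
    sprintf("- RPMM terminal classes: %d", result$rpmm$n_classes),
    sprintf("- bioinformatic classes with >= 1 locus: %d",
            nrow(result$bio_classes$census)),
    "",
    "## Omnibus max-|t| tests",
    vapply(names(result$omnibus), function(nm) {
      g <- glance(result$omnibus[[nm]])
      sprintf("- %s: max |t| = %.2f, p = %.4g, null limit = %.2f (B = %d)",
              nm, g$max_t, g$p_value, g$null_limit, g$B)
    }, character(1)),
    "",
    if (!is.null(result$gsea)) c(
      "## GSEA (top set per marker)",
      vapply(names(result$gsea), function(nm) {
        top <- tidy(result$gsea[[nm]])[1, ]
        sprintf("- %s: %s (size %d), NES = %.2f, p = %.3g, q = %.3g",
                nm, top$set, top$size, top$nes, top$p_value, top$fdr_q)
      }, character(1))
    ) else "## GSEA skipped (no sets passed the size filter)")
}

#' @export
print.betaclass_pipeline <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
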