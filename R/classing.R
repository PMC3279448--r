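# canonical attribute order of the bioinformatic class key
.bio_attributes <- c("cgi", "pcg_target", "tfbs",
                     "rep_alu", "rep_line1", "rep_line2", "rep_mir")

#' Assign loci to bioinformatic attribute classes
#'
#' Groups CpG loci by their tuple of seven binary genomic attributes, in
#' the fixed canonical order CGI, PcG target, TFBS proximity, Alu, LINE-1,
#' LINE-2, MIR. The class key is the attribute names joined with `"/"`
#' (e.g. `"CGI/PcG/TFBS"`); the all-false tuple is labelled `"none"`. Only
#' classes containing at least one locus appear in the census.
#'
#' @param annotation Locus annotation tibble (see [simulate_annotation()]
#'   or [read_annotation()]) with logical columns `cgi`, `pcg_target`,
#'   `tfbs`, `rep_alu`, `rep_line1`, `rep_line2`, `rep_mir`.
#' @return A list: `assignment` (tibble `locus_id`, `class` key string)
#'   and `census` (tibble `class`, `n_loci`, ordered by size descending).
#' @examples
#' ann <- simulate_annotation(sim_config(n_loci = 500, seed = 5))
#' bc <- assign_bioinformatic_classes(ann)
#' nrow(bc$census)
#' @export
assign_bioinformatic_classes <- function(annotation) {
  miss <- setdiff(c("locus_id", .bio_attributes), names(annotation))
  if (length(miss)) {
    abort(paste("annotation is missing columns:",
                paste(miss, collapse = ", ")))
  }
  flags <- as.matrix(as.data.frame(annotation[.bio_attributes]))
  if (!is.logical(flags)) abort("attribute columns must be logical")
  pretty <- c("CGI", "PcG", "TFBS", "Alu", "LINE-1", "LINE-2", "MIR")
  key <- apply(flags, 1, function(f) {
    if (!any(f)) "none" else paste(pretty[f], collapse = "/")
  })
  assignment <- tibble(locus_id = annotation$locus_id, class = key)
  census <- assignment |>
    dplyr::count(.data$class, name = "n_loci") |>
    dplyr::arrange(dplyr::desc(.data$n_loci), .data$class)
  list(assignment = assignment, census = census)
}

#' Per-subject aggregate class methylation
#'
#' For every subject and every class, the unweighted mean beta-value over
#' the class's member loci. Works for both classing schemes: RPMM classes
#' (integer labels) and bioinformatic classes (key strings).
#'
#' @param beta Numeric matrix, loci x subjects, locus IDs as rownames.
#' @param classes Either a tibble with columns `locus_id` and `class`, or
#'   a vector of class labels named by (or aligned with) the matrix rows.
#' @return A tibble of class `"class_aggregate"`: one row per subject,
#'   `subject_id` plus one column per nonempty class, values in `[0, 1]`.
#'   Classes present in `classes` but matching no matrix locus are dropped
#'   with a warning.
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 200, seed = 1),
#'                             n_subjects = 10)
#' agg <- aggregate_class_methylation(sim$beta, sim$truth |>
#'   dplyr::rename(class = latent_class))
#' dim(agg)
#' @export
aggregate_class_methylation <- function(beta, classes) {
  check_beta_matrix(beta)
  if (is.null(rownames(beta))) abort("beta matrix must have locus rownames")
  if (is.data.frame(classes)) {
    if (!all(c("locus_id", "class") %in% names(classes))) {
      abort("classes data frame needs columns locus_id and class")
    }
    lab <- classes$class[match(rownames(beta), classes$locus_id)]
  } else {
    lab <- if (!is.null(names(classes))) {
      classes[rownames(beta)]
    } else {
      if (length(classes) != nrow(beta)) {
        abort("unnamed class vector must have one label per matrix row")
      }
      classes
    }
  }
  if (anyNA(lab)) {
    abort("class map does not cover all matrix loci")
  }
  lab <- as.character(lab)
  lv <- unique(lab)
  if (is.data.frame(classes)) {
    empty <- setdiff(unique(as.character(classes$class)), lv)
    if (length(empty)) {
      warn(paste("classes with no loci in the matrix were excluded:",
                 paste(empty, collapse = ", ")))
    }
  }
  # keep numeric class labels in numeric order, others alphabetical
  lv <- if (!anyNA(suppressWarnings(as.numeric(lv)))) {
    lv[order(as.numeric(lv))]
  } else {
    sort(lv)
  }
  agg <- vapply(lv, function(cl) {
    colMeans(beta[lab == cl, , drop = FALSE])
  }, numeric(ncol(beta)))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = ncol(beta))
  out <- as_tibble(agg, .name_repair = "minimal")
  names(out) <- lv
  out <- dplyr::bind_cols(tibble(subject_id = colnames(beta)), out)
  class(out) <- c("class_aggregate", class(out))
  out
}
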