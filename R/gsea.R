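# Gene-set enrichment of TFBS identities among loci whose methylation
# tracks a repeat-element marker: weighted Kolmogorov-Smirnov running sum
# over the t-ranked locus list, significance by phenotype (marker)
# permutation, which preserves the inter-locus correlation structure.

#' Per-locus association statistics with a repeat marker
#'
#' Simple-regression t-statistic of each locus's beta-value on the
#' per-subject marker, ranked by descending t (rank 1 = strongest positive
#' association). Ties are broken by locus ID so the ranking is stable.
#' Zero-variance loci get t = 0.
#'
#' @param beta Numeric matrix, loci x subjects, locus IDs as rownames.
#' @param marker Per-subject marker values aligned with the columns (or
#'   named by subject ID).
#' @return A tibble: `locus_id`, `t`, `rank`, sorted by rank.
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 100, seed = 1),
#'                             n_subjects = 20)
#' locus_association_stats(sim$beta, rnorm(20, 50, 5))
#' @export
locus_association_stats <- function(beta, marker) {
  check_beta_matrix(beta)
  if (is.null(rownames(beta))) abort("beta matrix must have locus rownames")
  marker <- align_marker(marker, colnames(beta))
  n <- ncol(beta)
  if (n < 10) abort("need at least 10 subjects")
  t_stat <- locus_t(beta, marker)
  ord <- order(-t_stat, rownames(beta))
  tibble(locus_id = rownames(beta)[ord],
         t = t_stat[ord],
         rank = seq_along(t_stat))
}

locus_t <- function(beta, marker) {
  r <- suppressWarnings(as.numeric(cor(marker, t(beta))))
  r[!is.finite(r)] <- 0
  cor_to_t(r, length(marker))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked locus list accumulating `|t|^exponent` (normalised by
#' the member total) at member loci and subtracting `1/(N - m)` at
#' non-members; the enrichment score is the signed maximum deviation of
#' this running sum from zero. With `exponent = 0` this is the classical
#' KS statistic.
#'
#' @param ranked_stats A tibble from [locus_association_stats()] (columns
#'   `locus_id`, `t`, in rank order), or a named numeric vector of
#'   statistics already sorted in rank order.
#' @param members Character vector of member locus IDs; must be a
#'   nonempty strict subset of the ranked loci.
#' @param exponent Weight exponent on `|t|` (default 1).
#' @return A tibble: `es` (in `[-1, 1]`), `peak` (rank position of the
#'   extreme deviation).
#' @examples
#' stats <- locus_association_stats(
#'   simulate_beta_matrix(sim_config(n_loci = 50, seed = 1),
#'                        n_subjects = 15)$beta,
#'   rnorm(15))
#' enrichment_score(stats, stats$locus_id[1:5])
#' @export
enrichment_score <- function(ranked_stats, members, exponent = 1) {
  if (is.data.frame(ranked_stats)) {
    ids <- ranked_stats$locus_id
    s <- ranked_stats$t
  } else {
    ids <- names(ranked_stats)
    s <- as.numeric(ranked_stats)
  }
  if (is.null(ids)) abort("ranked statistics must carry locus IDs")
  if (length(members) == 0) abort("member set is empty")
  is_member <- ids %in% members
  if (all(is_member)) abort("member set cannot contain every ranked locus")
  if (!all(members %in% ids)) {
    abort("some members are not in the ranked list")
  }
  res <- running_sum_es(s, is_member, exponent)
  tibble(es = res$es, peak = res$peak)
}

running_sum_es <- function(s, is_member, exponent) {
  n <- length(s)
  m <- sum(is_member)
  w <- abs(s)^exponent
  denom <- sum(w[is_member])
  hit <- if (denom > 0) cumsum(w * is_member) / denom else
    cumsum(is_member) / m
  miss <- cumsum(!is_member) / (n - m)
  dev <- hit - miss
  peak <- which.max(abs(dev))
  list(es = dev[peak], peak = peak, running = dev)
}

# ES for every set (list of logical-index vectors) given unsorted stats
all_set_es <- function(t_stat, ids, sets_members, exponent) {
  ord <- order(-t_stat, ids)
  s <- t_stat[ord]
  vapply(sets_members, function(memb) {
    running_sum_es(s, memb[ord], exponent)$es
  }, numeric(1))
}

#' Extract TFBS locus sets from an annotation table
#'
#' Inverts the per-locus `tfbs_factors` list-column into one locus set per
#' named transcription factor, keeping sets within the size bounds.
#'
#' @param annotation Annotation tibble with `locus_id` and list-column
#'   `tfbs_factors`.
#' @param min_set_size,max_set_size Inclusive size bounds (defaults 5 and
#'   500).
#' @return Named list of character vectors of locus IDs.
#' @export
tfbs_sets <- function(annotation, min_set_size = 5, max_set_size = 500) {
  if (!all(c("locus_id", "tfbs_factors") %in% names(annotation))) {
    abort("annotation needs locus_id and tfbs_factors columns")
  }
  long <- tidyr::unnest(annotation[c("locus_id", "tfbs_factors")],
                        "tfbs_factors")
  sets <- split(long$locus_id, long$tfbs_factors)
  sizes <- lengths(sets)
  sets[sizes >= min_set_size & sizes <= max_set_size]
}

#' GSEA of TFBS sets by phenotype permutation
#'
#' Ranks all loci by their association t-statistic with the marker,
#' computes each TFBS set's weighted-KS enrichment score, and builds the
#' null by shuffling the marker across subjects (phenotype permutation,
#' which leaves the locus-locus correlation intact), recomputing all locus
#' statistics and set scores per permutation. The normalised enrichment
#' score (NES) divides each ES by the mean |null ES| of the same sign for
#' that set; p-values use the add-one same-sign tail count, and FDR q is
#' the permutation NES-based estimate: the fraction of pooled same-sign
#' null NES at least as extreme, divided by the fraction of observed
#' same-sign NES at least as extreme, capped at 1.
#'
#' @inheritParams locus_association_stats
#' @param sets Named list of locus-ID sets (see [tfbs_sets()]), or an
#'   annotation tibble from which sets are extracted.
#' @param B Number of marker permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param exponent Weight exponent on `|t|` (default 1).
#' @param min_set_size,max_set_size Size filter applied to `sets`.
#' @return An object of class `"gsea_result"`: a tibble `set`, `size`,
#'   `es`, `nes`, `p_value`, `fdr_q`, sorted by p then |NES|, with `B`,
#'   `seed` and `exponent` as attributes.
#' @examples
#' cfg <- sim_config(n_loci = 300, seed = 2)
#' sim <- simulate_beta_matrix(cfg, n_subjects = 20)
#' ann <- simulate_annotation(cfg, seed = 3)
#' res <- gsea_permutation(sim$beta, rnorm(20, 50, 5), ann,
#'                         B = 100, seed = 4)
#' head(tidy(res))
#' @export
gsea_permutation <- function(beta, marker, sets, B = 1000, seed = NULL,
                             exponent = 1, min_set_size = 5,
                             max_set_size = 500) {
  if (B < 100) abort("B must be at least 100")
  check_beta_matrix(beta)
  if (is.data.frame(sets)) {
    sets <- tfbs_sets(sets, min_set_size, max_set_size)
  } else {
    sets <- sets[lengths(sets) >= min_set_size &
                   lengths(sets) <= max_set_size]
  }
  if (length(sets) == 0) abort("no sets survive the size filter")
  ids <- rownames(beta)
  n_all <- length(ids)
  bad <- vapply(sets, function(s) length(setdiff(s, ids)) > 0 ||
                  length(s) >= n_all, logical(1))
  if (any(bad)) {
    abort(paste("sets with unknown loci or spanning every locus:",
                paste(names(sets)[bad], collapse = ", ")))
  }
  marker <- align_marker(marker, colnames(beta))
  n <- length(marker)
  members <- lapply(sets, function(s) ids %in% s)

  t_obs <- locus_t(beta, marker)
  es_obs <- all_set_es(t_obs, ids, members, exponent)

  if (!is.null(seed)) set.seed(seed)
  es_null <- matrix(NA_real_, B, length(sets))
  for (bb in seq_len(B)) {
    mp <- marker[sample.int(n)]
    tp <- locus_t(beta, mp)
    es_null[bb, ] <- all_set_es(tp, ids, members, exponent)
  }

  res <- purrr::map_dfr(seq_along(sets), function(j) {
    null_j <- es_null[, j]
    same <- if (es_obs[j] >= 0) null_j[null_j >= 0] else null_j[null_j < 0]
    denom <- mean(abs(same))
    nes <- if (is.finite(denom) && denom > 0) es_obs[j] / denom else NA_real_
    p <- (1 + sum(abs(same) >= abs(es_obs[j]))) / (length(same) + 1)
    tibble(set = names(sets)[j], size = sum(members[[j]]),
           es = es_obs[j], nes = nes, p_value = p)
  })

  res$fdr_q <- gsea_fdr(res$nes, es_null_to_nes(es_null))
  res <- dplyr::arrange(res, .data$p_value, dplyr::desc(abs(.data$nes)))
  structure(res, B = B, seed = seed, exponent = exponent,
            class = c("gsea_result", class(res)))
}

# normalise the null ES matrix column-wise by same-sign means
es_null_to_nes <- function(es_null) {
  apply(es_null, 2, function(col) {
    pos <- mean(col[col >= 0])
    neg <- mean(abs(col[col < 0]))
    out <- numeric(length(col))
    out[col >= 0] <- if (is.finite(pos) && pos > 0) col[col >= 0] / pos else 0
    out[col < 0] <- if (is.finite(neg) && neg > 0) col[col < 0] / neg else 0
    out
  })
}

# permutation FDR on the NES scale, positive and negative sides separately
gsea_fdr <- function(nes_obs, nes_null) {
  null_pool <- as.numeric(nes_null)
  vapply(nes_obs, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(null_pool[null_pool >= 0] >= v)
      den <- mean(nes_obs[nes_obs >= 0] >= v)
    } else {
      num <- mean(null_pool[null_pool < 0] <= v)
      den <- mean(nes_obs[nes_obs < 0] <= v)
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))
}

#' @describeIn gsea_permutation Result table as a plain tibble.
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gsea_result")
  as_tibble(out)
}
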