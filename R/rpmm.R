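# Recursively partitioned beta-mixture clustering of CpG loci.
#
# Loci are items, subjects are features. Each mixture component models a
# locus's beta-values as independent beta variates, one (a_j, b_j) pair per
# subject column. Nodes are split 2-ways by weighted EM; a split is kept
# only if it improves BIC; recursion stops after max_depth splits.

.clip_eps <- 1e-4

clip_beta <- function(x, eps = .clip_eps) pmin(pmax(x, eps), 1 - eps)

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

# Weighted per-subject beta MLE from sufficient statistics.
# For each subject column j: weighted mean of log x and log(1-x) determine
# (a_j, b_j) via Newton iterations on the digamma system, started at the
# method-of-moments estimate. All subjects are updated simultaneously
# (vectorised over j). Exact MLE keeps the EM monotone.
beta_mle_columns <- function(X, LX, L1X, w, newton_iter = 40L,
                             grad_tol = 1e-10) {
  sw <- sum(w)
  m <- as.numeric(crossprod(w, X)) / sw
  m2 <- as.numeric(crossprod(w, X^2)) / sw
  v <- pmax(m2 - m^2, 1e-8)
  t1 <- as.numeric(crossprod(w, LX)) / sw
  t2 <- as.numeric(crossprod(w, L1X)) / sw

  common <- pmax(m * (1 - m) / v - 1, 1e-3)
  a <- pmax(m * common, 1e-3)
  b <- pmax((1 - m) * common, 1e-3)

  for (it in seq_len(newton_iter)) {
    dab <- digamma(a + b)
    g1 <- t1 - (digamma(a) - dab)
    g2 <- t2 - (digamma(b) - dab)
    if (max(abs(c(g1, g2))) < grad_tol) break
    tab <- trigamma(a + b)
    h11 <- trigamma(a) - tab
    h22 <- trigamma(b) - tab
    det <- h11 * h22 - tab^2
    det[det < 1e-12] <- 1e-12
    da <- (h22 * g1 + tab * g2) / det
    db <- (tab * g1 + h11 * g2) / det
    step <- rep(1, length(a))
    for (k in 1:30) {
      bad <- (a + step * da <= 1e-6) | (b + step * db <= 1e-6)
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    a <- a + step * da
    b <- b + step * db
  }
  list(a = a, b = b)
}

# log-likelihood of every locus under per-subject beta shapes (a, b)
node_loglik_vec <- function(LX, L1X, a, b) {
  as.numeric(LX %*% (a - 1) + L1X %*% (b - 1)) - sum(lbeta(a, b))
}

fit_beta_node <- function(X, LX, L1X, w) {
  par <- beta_mle_columns(X, LX, L1X, w)
  llv <- node_loglik_vec(LX, L1X, par$a, par$b)
  list(a = par$a, b = par$b, loglik = sum(w * llv))
}

#' Weighted EM for a K-component per-subject beta mixture
#'
#' Fits a mixture of K components to the rows (loci) of a beta-value
#' matrix, each component modelling every subject column with its own beta
#' distribution. The E-step computes responsibilities from products of
#' per-subject beta densities (via log-sum-exp); the M-step re-estimates
#' each component's per-subject shapes by exact weighted maximum
#' likelihood (Newton on the digamma system, method-of-moments start), so
#' the observed-data log-likelihood is nondecreasing across iterations.
#' Initialisation splits the loci at the weighted median of their mean
#' methylation, making the fit deterministic.
#'
#' @param beta Numeric matrix, loci x subjects, values in `[0, 1]` (clipped
#'   to `[1e-4, 1 - 1e-4]` before likelihood evaluation).
#' @param weights Per-locus nonnegative weights (membership of the node
#'   being split); default all 1.
#' @param K Number of components (2 for tree splits).
#' @param tol Relative log-likelihood change at which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param min_weight Minimum mixing proportion; below it the component is
#'   declared degenerate and a single-component fallback is returned.
#' @return A list: `pi` (mixing weights), `a`, `b` (K x subjects shape
#'   matrices), `resp` (loci x K responsibilities), `loglik`,
#'   `loglik_trace`, `converged`, `fallback` (TRUE when a component
#'   degenerated and the single-component fit is returned).
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 100,
#'                                        n_latent_classes = 2, seed = 1),
#'                             n_subjects = 10)
#' fit <- fit_beta_mixture_em(sim$beta)
#' fit$pi
#' @export
fit_beta_mixture_em <- function(beta, weights = NULL, K = 2,
                                tol = 1e-6, max_iter = 500,
                                min_weight = 1e-3) {
  check_beta_matrix(beta)
  n <- nrow(beta)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) {
    abort("weights must be nonnegative, one per locus")
  }
  if (sum(weights > 1e-8) < 2 * K) {
    abort(sprintf("need at least %d loci with nonzero weight", 2 * K))
  }
  X <- clip_beta(beta)
  LX <- log(X)
  L1X <- log1p(-X)

  # deterministic init: weighted quantile split of locus means
  lm_ <- rowMeans(X)
  o <- order(lm_)
  cw <- cumsum(weights[o]) / sum(weights)
  grp_sorted <- pmin(findInterval(cw, seq_len(K - 1) / K,
                                  left.open = TRUE) + 1L, K)
  grp <- integer(n)
  grp[o] <- grp_sorted
  R <- matrix(1e-6, n, K)
  R[cbind(seq_len(n), grp)] <- 1
  R <- R / rowSums(R)

  single <- NULL
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  a <- b <- matrix(NA_real_, K, ncol(X))
  pi_k <- rep(1 / K, K)

  for (iter in seq_len(max_iter)) {
    # M-step
    for (k in seq_len(K)) {
      wk <- weights * R[, k]
      if (sum(wk) < 1e-10) wk <- weights * 1e-6
      par <- beta_mle_columns(X, LX, L1X, wk)
      a[k, ] <- par$a
      b[k, ] <- par$b
    }
    pi_k <- as.numeric(crossprod(R, weights))
    pi_k <- pi_k / sum(pi_k)

    if (any(pi_k < min_weight)) {
      single <- fit_beta_node(X, LX, L1X, weights)
      return(list(pi = 1, a = matrix(single$a, 1), b = matrix(single$b, 1),
                  resp = matrix(1, n, 1), loglik = single$loglik,
                  loglik_trace = loglik_trace, converged = TRUE,
                  fallback = TRUE))
    }

    # E-step
    L <- vapply(seq_len(K),
                function(k) node_loglik_vec(LX, L1X, a[k, ], b[k, ]) +
                  log(pi_k[k]),
                numeric(n))
    mx <- apply(L, 1, max)
    lse <- mx + log(rowSums(exp(L - mx)))
    R <- exp(L - lse)
    ll <- sum(weights * lse)
    loglik_trace <- c(loglik_trace, ll)

    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) < tol * (abs(prev_ll) + 1e-3)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }

  list(pi = pi_k, a = a, b = b, resp = R, loglik = ll,
       loglik_trace = loglik_trace, converged = converged, fallback = FALSE)
}

# BIC of a fitted node/mixture; effective sample size = total membership
node_bic <- function(loglik, n_par, n_eff) -2 * loglik + n_par * log(n_eff)

#' Recursively partitioned beta-mixture clustering
#'
#' Builds a binary tree over CpG loci: at each node a 2-component
#' per-subject beta mixture is fitted by [fit_beta_mixture_em()] and the
#' split is accepted only when the mixture's BIC improves on the
#' single-component BIC of the same loci (parameter counts: 2 shapes per
#' subject per component plus one mixing weight). Accepted children are
#' split recursively until `max_depth` (default four splits, so at most 16
#' terminal classes). Loci are hard-assigned to their
#' maximum-responsibility terminal node, and terminal classes are
#' renumbered so class 1 has the lowest mean methylation.
#'
#' @inheritParams fit_beta_mixture_em
#' @param max_depth Maximum number of recursive splits (tree depth).
#' @param min_node Minimum hard size of a node eligible for splitting.
#' @return An object of class `"rpmm"`: list with `assignment` (tibble
#'   `locus_id`, `class`), `class_summary` (tibble `class`, `n_loci`,
#'   `mean_beta`), `n_classes`, `tree` (nested list of node labels, BICs
#'   and split decisions), and `loglik_traces` (per-node EM traces).
#' @examples
#' sim <- simulate_beta_matrix(sim_config(n_loci = 300,
#'                                        n_latent_classes = 4, seed = 1),
#'                             n_subjects = 20)
#' fit <- rpmm_fit(sim$beta, max_depth = 2)
#' fit$n_classes
#' @export
rpmm_fit <- function(beta, max_depth = 4, tol = 1e-6, max_iter = 500,
                     min_weight = 1e-3, min_node = 4) {
  check_beta_matrix(beta)
  if (nrow(beta) < 2) abort("need at least 2 loci")
  X <- clip_beta(beta)
  LX <- log(X)
  L1X <- log1p(-X)
  n <- nrow(X)
  S <- ncol(X)

  terminals <- list()
  traces <- list()

  grow <- function(w, label, depth) {
    n_eff <- sum(w)
    node_fit <- fit_beta_node(X, LX, L1X, w)
    bic_single <- node_bic(node_fit$loglik, 2 * S, n_eff)
    node <- list(label = label, depth = depth, n_eff = n_eff,
                 bic_single = bic_single, split = FALSE)

    can_split <- depth < max_depth && sum(w > 0.5) >= min_node &&
      sum(w > 1e-8) >= 4
    if (can_split) {
      em <- fit_beta_mixture_em(beta, weights = w, K = 2, tol = tol,
                                max_iter = max_iter,
                                min_weight = min_weight)
      traces[[paste0("node", label, "_")]] <<- em$loglik_trace
      if (!em$fallback) {
        bic_split <- node_bic(em$loglik, 4 * S + 1, n_eff)
        node$bic_split <- bic_split
        if (bic_split < bic_single) {
          node$split <- TRUE
          node$children <- list(
            grow(w * em$resp[, 1], paste0(label, "0"), depth + 1),
            grow(w * em$resp[, 2], paste0(label, "1"), depth + 1)
          )
          return(node)
        }
      }
    }
    terminals[[length(terminals) + 1]] <<- list(label = label, weight = w)
    node
  }

  tree <- grow(rep(1, n), "", 0)

  W <- vapply(terminals, function(t) t$weight, numeric(n))
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  raw_class <- max.col(W, ties.method = "first")

  # membership-weighted class means (always defined, even for classes with
  # no argmax loci), used for ordering
  locus_mean <- rowMeans(beta)
  means <- as.numeric(crossprod(W, locus_mean)) / pmax(colSums(W), 1e-12)
  sizes <- tabulate(raw_class, nbins = length(terminals))
  relabel <- order_classes(means, sizes)
  class_id <- relabel[raw_class]

  kfin <- length(terminals)
  summary_tb <- tibble(class = seq_len(kfin)) |>
    dplyr::mutate(
      n_loci = tabulate(class_id, nbins = kfin),
      mean_beta = vapply(seq_len(kfin), function(k) {
        mean(beta[class_id == k, , drop = FALSE])
      }, numeric(1))
    )

  structure(list(
    assignment = tibble(locus_id = rownames(beta) %||%
                          sprintf("L%05d", seq_len(n)),
                        class = class_id),
    class_summary = summary_tb,
    n_classes = kfin,
    tree = tree,
    loglik_traces = traces
  ), class = "rpmm")
}

#' Order methylation classes by increasing mean methylation
#'
#' Returns the relabelling that assigns class 1 to the lowest-methylation
#' class and the highest number to the most methylated; ties in mean are
#' broken by class size, larger classes getting the lower index.
#'
#' @param means Per-class mean methylation (fraction), indexed by current
#'   class label.
#' @param sizes Per-class locus counts (used only to break ties); defaults
#'   to equal sizes.
#' @return Integer vector `relabel` such that `relabel[old_class]` is the
#'   ordered class label.
#' @examples
#' order_classes(c(0.8, 0.1, 0.5))  # c(3, 1, 2)
#' @export
order_classes <- function(means, sizes = rep(1, length(means))) {
  if (length(sizes) != length(means)) {
    abort("sizes must match means in length")
  }
  o <- order(means, -sizes)
  relabel <- integer(length(means))
  relabel[o] <- seq_along(means)
  relabel
}

#' @export
print.rpmm <- function(x, ...) {
  cat(sprintf("<rpmm> %d terminal classes over %d loci\n",
              x$n_classes, nrow(x$assignment)))
  print(x$class_summary, n = x$n_classes)
  invisible(x)
}

#' @describeIn rpmm_fit Per-locus class assignment as a tibble.
#' @param x An `rpmm` object.
#' @param ... Unused.
#' @method tidy rpmm
#' @export
tidy.rpmm <- function(x, ...) x$assignment

#' @describeIn rpmm_fit One-row fit summary (`n_classes`, `n_loci`,
#'   `mean_beta`).
#' @method glance rpmm
#' @export
glance.rpmm <- function(x, ...) {
  tibble(n_classes = x$n_classes, n_loci = nrow(x$assignment),
         mean_beta = sum(x$class_summary$n_loci * x$class_summary$mean_beta) /
           nrow(x$assignment))
}
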