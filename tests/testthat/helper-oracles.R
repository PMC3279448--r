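# Independent brute-force oracles used to cross-check the package
# implementations on small instances. These deliberately share no code
# with the package.

# squared Mahalanobis distance by direct matrix algebra
oracle_mahalanobis <- function(S) {
  mu <- colMeans(S)
  Sigma_inv <- solve(cov(S))
  apply(S, 1, function(x) as.numeric(t(x - mu) %*% Sigma_inv %*% (x - mu)))
}

# Kruskal-Wallis H from the rank-sum formula with tie correction
oracle_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# weighted-KS enrichment score by an explicit element-by-element walk
oracle_enrichment_score <- function(stats_in_rank_order, is_member, p) {
  n <- length(stats_in_rank_order)
  m <- sum(is_member)
  nr <- sum(abs(stats_in_rank_order[is_member])^p)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (is_member[i]) {
      cur <- cur + abs(stats_in_rank_order[i])^p / nr
    } else {
      cur <- cur - 1 / (n - m)
    }
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# per-locus simple-regression t statistic via lm(), one locus at a time
oracle_locus_t <- function(beta_row, marker) {
  fit <- summary(lm(beta_row ~ marker))
  unname(fit$coefficients["marker", "t value"])
}

# small fixed cohort for matching tests
toy_subjects <- function(...) {
  tibble::tribble(~subject_id, ~sex, ~maternal_age, ~gestational_age, ...)
}
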