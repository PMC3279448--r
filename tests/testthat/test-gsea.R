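test_that("locus statistics rank an affine locus first and are stable", {
  set.seed(131)
  m <- matrix(rbeta(50 * 20, 3, 9), 50, 20,
              dimnames = list(sprintf("cg%03d", 1:50),
                              sprintf("S%02d", 1:20)))
  marker <- rnorm(20, 50, 5)
  m["cg007", ] <- pmin(pmax(0.002 * marker + 0.1, 0), 1)
  stats <- locus_association_stats(m, marker)
  expect_equal(stats$locus_id[1], "cg007")
  expect_equal(stats$rank, seq_len(50))
  expect_true(all(diff(stats$t) <= 0))

  # two identical loci: identical statistics, adjacent ranks by ID
  m2 <- m
  m2["cg020", ] <- m2["cg010", ]
  s2 <- locus_association_stats(m2, marker)
  r10 <- which(s2$locus_id == "cg010")
  expect_equal(s2$locus_id[r10 + 1], "cg020")
  expect_equal(s2$t[r10], s2$t[r10 + 1])

  # per-locus t agrees with lm
  expect_equal(stats$t[stats$locus_id == "cg003"],
               oracle_locus_t(m["cg003", ], marker), tolerance = 1e-8)
})

test_that("statistics are symmetric about zero for an independent marker", {
  set.seed(137)
  m <- matrix(rbeta(300 * 30, 3, 9), 300, 30,
              dimnames = list(sprintf("cg%03d", 1:300), NULL))
  colnames(m) <- sprintf("S%02d", 1:30)
  stats <- locus_association_stats(m, rnorm(30, 50, 5))
  expect_lt(abs(mean(stats$t)), 0.15)
  expect_lt(abs(mean(stats$t > 0) - 0.5), 0.08)
})

test_that("enrichment score matches the worked running-sum oracle", {
  # 10-locus worked example, 3-member set, weight p = 1
  t_ranked <- c(3.2, 2.5, 1.9, 1.2, 0.7, -0.3, -0.9, -1.4, -2.1, -2.8)
  ids <- sprintf("L%02d", 1:10)
  ranked <- tibble::tibble(locus_id = ids, t = t_ranked)
  members <- ids[c(1, 2, 9)]
  es <- enrichment_score(ranked, members, exponent = 1)
  oracle <- oracle_enrichment_score(t_ranked, ids %in% members, 1)
  expect_equal(es$es, oracle, tolerance = 1e-12)

  # members at the top with p = 0: ES is exactly 1 at the m-th position
  top <- enrichment_score(ranked, ids[1:3], exponent = 0)
  expect_equal(top$es, 1, tolerance = 1e-12)
  expect_equal(top$peak, 3)

  # uniformly interleaved members, p = 0: ES near 0
  inter <- enrichment_score(ranked, ids[c(2, 4, 6, 8, 10)], exponent = 0)
  expect_lt(abs(inter$es), 0.21)

  expect_error(enrichment_score(ranked, character(0)), "empty")
  expect_error(enrichment_score(ranked, ids), "every ranked locus")
  expect_error(enrichment_score(ranked, c("L01", "nope")), "not in the ranked")
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(139)
  t_ranked <- sort(rnorm(40), decreasing = TRUE)
  ids <- sprintf("L%02d", 1:40)
  member_idx <- c(2, 5, 6, 17, 30, 38)
  es <- enrichment_score(tibble::tibble(locus_id = ids, t = t_ranked),
                         ids[member_idx], exponent = 1)
  ref <- fgsea::calcGseaStat(t_ranked, selectedStats = member_idx,
                             gseaParam = 1, scoreType = "std")
  expect_equal(es$es, unname(ref), tolerance = 1e-8)
})

test_that("running sum is conservative and scale-invariant", {
  set.seed(149)
  s <- sort(rnorm(30), decreasing = TRUE)
  memb <- seq_len(30) %in% c(3, 7, 11, 25)
  walk <- betaclass:::running_sum_es(s, memb, 1)
  expect_equal(walk$running[30], 0, tolerance = 1e-12)

  # positive rescaling of the statistics leaves ES unchanged
  walk2 <- betaclass:::running_sum_es(3.7 * s, memb, 1)
  expect_equal(walk$es, walk2$es, tolerance = 1e-12)
  walk0 <- betaclass:::running_sum_es(s, memb, 0)
  walk0b <- betaclass:::running_sum_es(3.7 * s, memb, 0)
  expect_equal(walk0$es, walk0b$es, tolerance = 1e-12)
})

test_that("phenotype-permutation GSEA finds an injected signal and is
           well-calibrated under the null", {
  cfg <- sim_config(n_loci = 400, seed = 151)
  sim <- simulate_beta_matrix(cfg, n_subjects = 30)
  ann <- simulate_annotation(cfg, seed = 152)
  sets <- tfbs_sets(ann)
  expect_gt(length(sets), 5)

  set.seed(153)
  marker <- rnorm(30, 50, 5)

  # null run: per-set p-values roughly uniform
  res0 <- gsea_permutation(sim$beta, marker, sets, B = 100, seed = 154)
  expect_true(all(res0$p_value > 0 & res0$p_value <= 1))
  expect_gt(suppressWarnings(ks.test(res0$p_value, "punif"))$p.value, 0.001)
  expect_true(all(abs(res0$es) <= 1))

  # inject a marker association into every member of one set; disjoint
  # sets so the signal cannot leak into a co-occurring factor's set
  disjoint <- split(rownames(sim$beta)[1:200],
                    rep(sprintf("SET%02d", 1:10), each = 20))
  target <- "SET04"
  beta2 <- sim$beta
  idx <- rownames(beta2) %in% disjoint[[target]]
  shift <- 0.03 * scale(marker)[, 1]
  beta2[idx, ] <- pmin(pmax(sweep(beta2[idx, , drop = FALSE], 2, shift,
                                  "+"), 0), 1)
  res1 <- gsea_permutation(beta2, marker, disjoint, B = 200, seed = 155)
  expect_equal(tidy(res1)$set[1], target)
  expect_lte(tidy(res1)$p_value[1], 0.01)

  expect_error(gsea_permutation(sim$beta, marker, sets, B = 50),
               "at least 100")
  expect_error(gsea_permutation(sim$beta, marker,
                                list(tiny = sets[[1]][1:2])),
               "size filter")
})

test_that("set extraction respects the size window", {
  ann <- simulate_annotation(sim_config(n_loci = 500, seed = 157))
  sets <- tfbs_sets(ann, min_set_size = 5, max_set_size = 50)
  expect_true(all(lengths(sets) >= 5 & lengths(sets) <= 50))
  # every set member really is TFBS-proximal
  tf_loci <- ann$locus_id[ann$tfbs]
  expect_true(all(unlist(sets) %in% tf_loci))
})
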