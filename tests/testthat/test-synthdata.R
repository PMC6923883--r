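test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_genes = -5), "positive integers")
  expect_error(cohort_config(n_samples = 2), "positive integers")
  expect_error(cohort_config(tail_fraction = 0.5), "0, 0.5")
  expect_error(cohort_config(fraction_negative_skew = 1.2), "0, 1")
  expect_error(cohort_config(region_probabilities = c(Promoter = 0.5, UTR = 0.4, Body = 0.4)),
               "sum to 1")
  expect_error(cohort_config(target_corr = -1.5), "target_corr")
})

test_that("planted moments invert correctly and saturate", {
  pm <- planted_moments(3, 0.1, 1)
  expect_equal(pm[["variance"]], 1 + 0.1 * 0.9 * 9)
  expect_equal(pm[["third_moment"]], 0.1 * 0.9 * 0.8 * 27)
  d <- delta_for_skewness(0.9, 0.1, 1)
  expect_equal(planted_moments(d, 0.1, 1)[["skewness"]], 0.9, tolerance = 1e-8)
  # the skewness of the two-component model saturates in delta
  expect_error(delta_for_skewness(2, 0.1, 1), "asymptote")
})

test_that("a symmetric generator yields centred, sign-balanced skewness", {
  cfg <- cohort_config(n_genes = 300, n_samples = 500, tail_fraction = 0,
                       tail_shift = 0, seed = 5)
  co <- generate_cohort(cfg)
  expect_true(all(co$truth$genes$direction == 0))
  expect_true(all(co$truth$genes$delta == 0))
  sk <- compute_skewness(co$expression)
  # per-gene |S| is O(0.4) under symmetry; the mean over 300 genes has
  # Monte-Carlo sd ~ 0.026, so 0.08 is a 3-sigma bound on centredness
  expect_lt(abs(mean(sk$skewness)), 0.08)
  expect_gt(gene_split(sk)$fraction_negative, 0.4)
  expect_lt(gene_split(sk)$fraction_negative, 0.6)
})

test_that("planted tails produce positive skew in nearly all replicate genes", {
  cfg <- cohort_config(n_genes = 250, n_samples = 500, tail_fraction = 0.1,
                       tail_shift = 3, fraction_negative_skew = 0, seed = 8)
  co <- generate_cohort(cfg)
  sk <- compute_skewness(co$expression)
  expect_gte(mean(sk$skewness > 0), 0.95)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_config(n_genes = 40, n_samples = 50, linked_fraction = 0.2,
                       seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$gene_sets, b$gene_sets)
})

test_that("mean planted |S| is monotone in tail shift and small tail fractions", {
  mean_abs_skew <- function(delta, pi_tail, seed) {
    cfg <- cohort_config(n_genes = 250, n_samples = 300,
                         tail_fraction = pi_tail, tail_shift = delta,
                         fraction_negative_skew = 0, seed = seed)
    mean(abs(compute_skewness(generate_cohort(cfg)$expression)$skewness))
  }
  by_delta <- vapply(c(1, 2, 3.5), mean_abs_skew, numeric(1),
                     pi_tail = 0.1, seed = 12)
  expect_true(all(diff(by_delta) > 0))
  # the model's skewness rises with the tail fraction only while the tail is
  # small (it peaks near pi ~ 0.1 at delta = 3 sd and declines after); test
  # the increasing regime and the closed-form peak location
  by_pi <- vapply(c(0.02, 0.05, 0.08), function(p) {
    mean_abs_skew(3, p, seed = 13)
  }, numeric(1))
  expect_true(all(diff(by_pi) > 0))
  s_of_pi <- vapply(c(0.05, 0.1, 0.3), function(p) {
    planted_moments(3, p)[["skewness"]]
  }, numeric(1))
  expect_gt(s_of_pi[2], s_of_pi[1])
  expect_lt(s_of_pi[3], s_of_pi[2])
})

test_that("cohort outputs are mutually consistent and truth is well-formed", {
  co <- linked_cohort()
  cfg <- co$config
  expect_equal(dim(co$expression), c(cfg$n_genes, cfg$n_samples))
  expect_equal(nrow(co$annotation), cfg$n_genes * cfg$n_probes_per_gene)
  expect_setequal(unique(co$annotation$gene_id), rownames(co$expression))
  expect_identical(rownames(co$methylation), co$annotation$probe_id)
  expect_identical(colnames(co$methylation), colnames(co$expression))
  truth <- co$truth$genes
  # tail size contract and direction/delta coherence
  k <- round(cfg$tail_fraction * cfg$n_samples)
  expect_true(all(lengths(co$truth$tails[truth$direction != 0]) == k))
  expect_true(all(truth$delta[truth$direction == 0] == 0))
  # linked genes carry a promoter shift opposite their skew direction
  linked <- truth[truth$linked, ]
  expect_true(all(sign(linked$dM_Promoter) == -linked$direction))
  expect_true(all(abs(linked$dM_Promoter) >=
                    cfg$magnitude_floor * abs(cfg$methyl_shift[["Promoter"]])))
  # the planted skewness/shift correlation is near its target (the sample
  # correlation over ~100 linked genes has Monte-Carlo sd ~ 0.036)
  expect_lt(abs(cor(linked$planted_skewness, linked$dM_Promoter) -
                  cfg$target_corr), 0.1)
  # gene sets reference cohort genes and include the planted enrichments
  expect_true(all(unlist(co$gene_sets) %in% rownames(co$expression)))
  expect_true(all(truth$direction[match(co$gene_sets$POS_SKEW_SET, truth$gene)] > 0))
  expect_true(all(truth$direction[match(co$gene_sets$NEG_SKEW_SET, truth$gene)] < 0))
})

test_that("planted tails are recovered by quantile splitting", {
  co <- linked_cohort()
  sk <- compute_skewness(co$expression)
  tails <- tail_split_cohort(co$expression, sk, method = "quantile",
                             q = co$config$tail_fraction)
  truth <- co$truth$genes
  linked <- truth$gene[truth$linked]
  jac <- vapply(linked, function(g) {
    found <- tails[[g]]$tail
    planted <- co$truth$tails[[g]]
    length(intersect(found, planted)) / length(union(found, planted))
  }, numeric(1))
  expect_gte(mean(jac >= 0.5), 0.95)
  expect_gte(mean(jac), 0.6)
})

test_that("convergence series generator matches its closed form", {
  s <- generate_convergence_series(0.2, 0.1, 0.3, sizes = c(10, 20, 30))
  expect_equal(s$split[1], 0.2 * exp(-1) + 0.3, tolerance = 1e-12)
  expect_equal(generate_convergence_series(0, 1, 0.4, sizes = 1:5)$split,
               rep(0.4, 5))
  big <- generate_convergence_series(0.2, 0.1, 0.3, sizes = c(10, 500))
  expect_equal(big$split[2], 0.3, tolerance = 1e-12)
  expect_error(generate_convergence_series(1, 1, 0, sizes = integer(0)),
               "non-empty")
  expect_error(generate_convergence_series(1, -1, 0, sizes = 1:3), "positive")
  s1 <- generate_convergence_series(0.2, 0.1, 0.3, 1:10, noise_sd = 0.01, seed = 4)
  s2 <- generate_convergence_series(0.2, 0.1, 0.3, 1:10, noise_sd = 0.01, seed = 4)
  expect_identical(s1, s2)
})
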