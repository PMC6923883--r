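test_that("beta to M-value conversion is the log2 logit", {
  expect_equal(beta_to_mvalue(0.5), 0)
  expect_equal(beta_to_mvalue(0.8), 2)
  expect_equal(beta_to_mvalue(0.2), -2)
  # clipping keeps the boundary finite
  expect_true(is.finite(beta_to_mvalue(0)))
  expect_equal(beta_to_mvalue(0), -beta_to_mvalue(1))
  expect_error(beta_to_mvalue(1.2), "0, 1")
  b <- matrix(c(0.5, 0.8, 0.2, 0.5), 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_equal(beta_to_mvalue(b),
               matrix(c(0, 2, -2, 0), 2, dimnames = dimnames(b)))
})

mini_meth_fixture <- function(tail_vals, nontail_vals, gene = "gA") {
  samples <- sprintf("s%02d", seq_len(length(tail_vals) + length(nontail_vals)))
  m <- matrix(c(tail_vals, nontail_vals), nrow = 1,
              dimnames = list("p1", samples))
  tails <- list(structure(list(
    direction = 1, tail = samples[seq_along(tail_vals)],
    non_tail = samples[-seq_along(tail_vals)],
    method = "quantile", param = 0.1, degenerate = FALSE
  ), class = "tail_assignment"))
  names(tails) <- gene
  ann <- data.frame(probe_id = "p1", gene_id = gene, region = "Promoter")
  list(meth = m, tails = tails, ann = ann)
}

test_that("probe tests reproduce the exact rank-sum tail probability", {
  fx <- mini_meth_fixture(c(5, 6, 7), c(1, 2, 3, 4))
  res <- probe_dm_test(fx$meth, fx$tails, fx$ann, min_tail = 3)
  # C(7,3) = 35 equally likely configurations; the observed one is extreme
  expect_equal(res$p, 2 / 35, tolerance = 1e-12)
  expect_equal(res$delta_m, 6 - 2.5)
  expect_equal(res$n_tail, 3)
  fx2 <- mini_meth_fixture(c(2, 2), c(0, 0))
  res2 <- probe_dm_test(fx2$meth, fx2$tails, fx2$ann, min_tail = 2)
  expect_equal(res2$delta_m, 2)
  # the only gene falls below the minimum tail size -> nothing testable
  expect_error(probe_dm_test(fx$meth, fx$tails, fx$ann, min_tail = 5),
               "no testable probes")
})

test_that("small-tail genes are skipped and BH spans all tested probes", {
  co <- linked_cohort()
  sk <- compute_skewness(co$expression)
  tails <- tail_split_cohort(co$expression, sk, "quantile", q = 0.1)
  # force one gene's tail below the minimum
  g1 <- names(tails)[1]
  tails[[g1]]$tail <- tails[[g1]]$tail[1:2]
  pr <- probe_dm_test(co$methylation, tails, co$annotation, min_tail = 5)
  expect_false(g1 %in% pr$gene)
  expect_equal(attr(pr, "n_genes_skipped_small_tail"), 1)
  expect_equal(pr$p_adj, p.adjust(pr$p, "BH"))
  expect_true(all(pr$n_tail + pr$n_nontail == ncol(co$methylation)))
})

test_that("gene summaries aggregate probes with the documented ordering", {
  res <- data.frame(
    probe = paste0("p", 1:5),
    gene = c("gA", "gA", "gA", "gB", "gB"),
    region = c("Promoter", "UTR", "Body", "Promoter", "Promoter"),
    n_tail = 10, n_nontail = 90,
    delta_m = c(-1, 0.5, -2, 1, 3),
    p = c(0.001, 0.1, 0.002, 0.001, 0.3),
    p_adj = c(0.005, 0.2, 0.008, 0.005, 0.5),
    stringsAsFactors = FALSE
  )
  skew <- data.frame(gene = c("gA", "gB"), skewness = c(0.7, -0.4))
  gs <- summarize_genes(res, skew, alpha = 0.01)
  a <- gs[gs$gene == "gA", ]
  expect_equal(a$min_adj_p, 0.005)
  expect_equal(a$frac_significant, 2 / 3)
  expect_equal(a$dM_Promoter, -1)
  expect_equal(a$dM_Body, -2)
  expect_true(is.na(a$dM_UTR))
  expect_equal(a$dM_All, mean(c(-1, -2)))
  # equal min p: gA ranks first by larger significant fraction
  expect_equal(gs$gene, c("gA", "gB"))
  b <- gs[gs$gene == "gB", ]
  expect_equal(b$frac_significant, 1 / 2)
  expect_equal(b$skewness, -0.4)
})

test_that("top-gene selection truncates or warns", {
  gs <- data.frame(gene = paste0("g", 1:30), min_adj_p = seq(0.001, 0.03, 0.001))
  expect_equal(nrow(select_top_genes(gs, 10)), 10)
  expect_equal(select_top_genes(gs, 1)$gene, "g1")
  expect_warning(all30 <- select_top_genes(gs, 500), "only 30")
  expect_equal(nrow(all30), 30)
})

test_that("quadrant analysis applies the sign rule and excludes boundaries", {
  top <- data.frame(
    gene = paste0("g", 1:7),
    skewness = c(0.3, -0.2, 0.5, -0.6, 0, 0.4, -0.1),
    dM_Promoter = c(-0.5, 0.4, 0.2, -0.3, 0.5, 0, 0.1),
    dM_UTR = NA_real_, dM_Body = NA_real_, dM_All = NA_real_
  )
  qa <- quadrant_analysis(top, regions = "Promoter")
  counts <- qa$counts
  expect_equal(counts[["S>0,dM<0"]], 1) # (0.3, -0.5)
  expect_equal(counts[["S<0,dM>0"]], 2) # (-0.2, 0.4), (-0.1, 0.1)
  expect_equal(counts[["S>0,dM>0"]], 1)
  expect_equal(counts[["S<0,dM<0"]], 1)
  expect_equal(counts[["n_boundary"]], 2) # the S=0 and dM=0 genes
  # quadrant counts sum to the included genes
  expect_equal(sum(counts[c("S<0,dM>0", "S>0,dM>0", "S<0,dM<0", "S>0,dM<0")]), 5)
})

test_that("region-pair Fisher tests match exhaustive enumeration", {
  # two disjoint gene groups so each region's quadrant counts are independent
  mk_genes <- function(region, n_in, n_out, offset) {
    # n_in genes in the (S>0, dM>0) quadrant, n_out in (S>0, dM<0)
    df <- data.frame(
      gene = paste0("q", offset + seq_len(n_in + n_out)),
      skewness = 1,
      dM_Promoter = NA_real_, dM_UTR = NA_real_, dM_Body = NA_real_,
      dM_All = NA_real_
    )
    df[[paste0("dM_", region)]] <- c(rep(1, n_in), rep(-1, n_out))
    df
  }
  top <- rbind(mk_genes("Promoter", 3, 1, 0), mk_genes("UTR", 1, 3, 10))
  qa <- quadrant_analysis(top, regions = c("Promoter", "UTR"))
  t_up <- qa$tests[qa$tests$quadrant == "S>0,dM>0", ]
  expect_equal(t_up$p, 34 / 70, tolerance = 1e-12)
  expect_equal(t_up$p, oracle_fisher_p(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               tolerance = 1e-12)
})

test_that("correlation confidence intervals follow the Fisher z transform", {
  # construct data with sample correlation exactly 0.8
  set.seed(33)
  n <- 500
  x <- rnorm(n)
  y0 <- rnorm(n)
  ex <- (x - mean(x)) / sd(x)
  ry <- residuals(lm(y0 ~ x))
  ry <- (ry - mean(ry)) / sd(ry)
  y <- 0.8 * ex + sqrt(1 - 0.64) * ry
  top <- data.frame(gene = paste0("g", 1:n), skewness = ex, dM_Promoter = y)
  cc <- correlation_with_ci(top, "Promoter")
  expect_equal(cc$r, 0.8, tolerance = 1e-10)
  expect_equal(cc$ci_lo, tanh(atanh(0.8) - qnorm(0.975) / sqrt(n - 3)),
               tolerance = 1e-10)
  expect_equal(c(cc$ci_lo, cc$ci_hi), c(0.766, 0.830), tolerance = 2e-3)
  # r = 0 gives an interval symmetric about zero
  top0 <- data.frame(gene = top$gene, skewness = ex, dM_Promoter = ry)
  cc0 <- correlation_with_ci(top0, "Promoter")
  expect_equal(cc0$r, 0, tolerance = 1e-10)
  expect_equal(cc0$ci_lo, -cc0$ci_hi, tolerance = 1e-10)
  # perfectly linear data are flagged degenerate
  topl <- data.frame(gene = paste0("g", 1:5), skewness = 1:5,
                     dM_Promoter = 2 * (1:5) + 3)
  ccl <- correlation_with_ci(topl, "Promoter")
  expect_true(ccl$degenerate)
  expect_equal(ccl$r, 1)
  expect_error(correlation_with_ci(top[1:3, ], "Promoter"), "at least 4")
  expect_error(
    correlation_with_ci(data.frame(gene = letters[1:5], skewness = rep(1, 5),
                                   dM_Promoter = rnorm(5)), "Promoter"),
    "zero variance")
})

test_that("false discovery stays controlled on half-null probe sets", {
  set.seed(60)
  n_probes <- 200
  n_rep <- 40
  fdrs <- vapply(seq_len(n_rep), function(r) {
    samples <- sprintf("s%03d", 1:100)
    tail_ids <- sample(samples, 20)
    tails <- list(gA = structure(list(
      direction = 1, tail = tail_ids, non_tail = setdiff(samples, tail_ids),
      method = "quantile", param = 0.2, degenerate = FALSE
    ), class = "tail_assignment"))
    m <- matrix(rnorm(n_probes * 100), n_probes,
                dimnames = list(sprintf("p%03d", 1:n_probes), samples))
    shifted <- 1:100 # first half carry a real 1.5-unit tail shift
    m[shifted, tail_ids] <- m[shifted, tail_ids] + 1.5
    ann <- data.frame(probe_id = rownames(m), gene_id = "gA",
                      region = "Promoter")
    pr <- probe_dm_test(m, tails, ann)
    called <- pr$probe[pr$p_adj < 0.01]
    if (length(called) == 0) return(0)
    mean(!called %in% sprintf("p%03d", shifted))
  }, numeric(1))
  expect_lte(mean(fdrs), 1.5 * 0.01)
})

test_that("cohort gene-set selection separates shared from unique genes", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"))
  iu <- intersect_and_unique(sets, n_unique = 1)
  expect_setequal(iu$shared, c("b", "c"))
  expect_equal(iu$unique$A, "a")
  expect_equal(iu$unique$B, "d")
  same <- suppressWarnings(
    intersect_and_unique(list(A = c("a", "b"), B = c("a", "b")), 1))
  expect_warning(intersect_and_unique(list(A = c("a", "b"), B = c("a", "b")), 1),
                 "only 0")
  expect_length(same$unique$A, 0)
  expect_error(intersect_and_unique(list(A = "a"), 1), "at least 2")
  big <- intersect_and_unique(list(A = c("x", "a", "b"), B = c("y", "a", "z")), 2)
  expect_equal(big$shared, "a")
  expect_equal(big$unique$A, c("x", "b"))
})

test_that("robustness sweep is stable for the planted promoter link", {
  co <- linked_cohort()
  sk <- compute_skewness(co$expression)
  tails <- tail_split_cohort(co$expression, sk, "quantile", q = 0.1)
  pr <- probe_dm_test(co$methylation, tails, co$annotation)
  gs <- summarize_genes(pr, sk)
  sweep <- robustness_sweep(gs, n_grid = seq(40, 120, 20))
  prom <- sweep[sweep$region == "Promoter", ]
  # the promoter correlation stays near the planted value across the grid
  expect_true(all(abs(prom$r - prom$r[1]) < 0.1))
  expect_true(all(abs(prom$r - co$config$target_corr) < 0.15))
  # no planted body link: correlation absent or much weaker than promoter
  body <- sweep[sweep$region == "Body", ]
  expect_true(all(is.na(body$r) | abs(body$r) < abs(prom$r)))
  # single grid point and window-1 smoothing are identities
  one <- robustness_sweep(gs, n_grid = 100, regions = "Promoter")
  expect_equal(nrow(one), 1)
  expect_equal(one$r, one$r_smooth)
  sm <- robustness_sweep(gs, n_grid = seq(40, 120, 20), regions = "Promoter",
                         smooth_window = 3)
  expect_equal(sm$r_smooth[1], mean(sm$r[1:2]))
  expect_equal(sm$r_smooth[3], mean(sm$r[2:4]))
})
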