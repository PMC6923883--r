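# Link expression-distribution tails to differential DNA methylation:
# per-probe tail vs non-tail rank-sum tests on M-values, BH correction across
# all tested probes, gene-level ranking, region-stratified quadrant and
# correlation analyses, robustness sweeps over the number of genes included,
# and cross-cohort gene-set selection.

#' Convert methylation beta-values to M-values
#'
#' M = log2(beta / (1 - beta)), with beta clipped to [eps, 1 - eps] so fully
#' methylated or unmethylated probes stay finite.
#'
#' @param beta numeric matrix of beta-values in [0, 1] (probes x samples).
#' @param eps clipping bound (default 1e-6).
#' @return matrix of M-values with the same dimnames.
#' @export
beta_to_mvalue <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta-values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(m) <- dimnames(beta)
  m
}

# rank-sum p-value with the exact/approximate policy: exact enumeration when
# the smaller group has <= `exact_limit` members, the total stays small
# enough for the exact null distribution to be cheap, and there are no ties;
# normal approximation with tie and continuity correction otherwise
ranksum_p <- function(a, b, exact_limit = 25, exact_total = 150) {
  exact <- min(length(a), length(b)) <= exact_limit &&
    (length(a) + length(b)) <= exact_total &&
    !anyDuplicated(c(a, b))
  stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
}

#' Per-probe tail vs non-tail differential methylation tests
#'
#' For every probe annotated to a gene with a tail assignment, runs a
#' two-sided Wilcoxon rank-sum test of tail vs non-tail M-values (exact for
#' small untied groups, normal approximation with continuity/tie correction
#' otherwise), records the mean M-value difference
#' dM = mean(tail) - mean(non-tail), and BH-adjusts across all tested probes
#' in the cohort jointly.
#'
#' @param meth probe x sample M-value matrix.
#' @param tails named list of "tail_assignment" objects (from
#'   [tail_split_cohort()]).
#' @param annotation data.frame probe_id, gene_id, region.
#' @param min_tail genes with fewer tail samples are skipped (default 5).
#' @return data.frame with columns probe, gene, region, n_tail, n_nontail,
#'   delta_m, p, p_adj; attributes `n_genes_skipped_small_tail` and
#'   `n_probes_skipped` (probes with < 2 values in a group).
#' @export
probe_dm_test <- function(meth, tails, annotation, min_tail = 5) {
  meth <- validate_matrix(meth, "methylation")
  annotation <- validate_annotation(annotation)
  samples <- colnames(meth)
  ann <- annotation[annotation$probe_id %in% rownames(meth) &
                      annotation$gene_id %in% names(tails), , drop = FALSE]
  tail_sizes <- vapply(tails, function(t) length(intersect(t$tail, samples)),
                       integer(1))
  small <- names(tails)[tail_sizes < min_tail]
  ann <- ann[!ann$gene_id %in% small, , drop = FALSE]

  n_skipped_probes <- 0L
  rows <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    g <- ann$gene_id[i]
    t_ids <- intersect(tails[[g]]$tail, samples)
    nt_ids <- intersect(tails[[g]]$non_tail, samples)
    mv <- meth[ann$probe_id[i], ]
    a <- mv[t_ids]
    b <- mv[nt_ids]
    if (length(a) < 2 || length(b) < 2) {
      n_skipped_probes <- n_skipped_probes + 1L
      next
    }
    rows[[i]] <- data.frame(
      probe = ann$probe_id[i], gene = g, region = ann$region[i],
      n_tail = length(a), n_nontail = length(b),
      delta_m = mean(a) - mean(b), p = ranksum_p(a, b),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no testable probes")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "n_genes_skipped_small_tail") <- length(small)
  attr(out, "n_probes_skipped") <- n_skipped_probes
  out
}

#' Gene-level summary of probe differential-methylation results
#'
#' Per gene: the adjusted p of its most significant probe, the fraction of
#' its probes significant at `alpha`, and the mean dM over significant probes
#' within each functional region (plus "All", the union of regions). Genes
#' are ordered by (min adjusted p ascending, fraction significant descending,
#' gene id) — the ranking used for top-N selection.
#'
#' @param results data.frame from [probe_dm_test()].
#' @param skew data.frame from [compute_skewness()] supplying S_g.
#' @param alpha per-probe adjusted-p significance level (default 0.01).
#' @return data.frame with columns gene, min_adj_p, n_probes,
#'   frac_significant, dM_All, dM_Promoter, dM_UTR, dM_Body, skewness.
#' @export
summarize_genes <- function(results, skew, alpha = 0.01) {
  if (nrow(results) == 0) stop("no probe results to summarize")
  sp <- split(results, results$gene)
  rows <- lapply(names(sp), function(g) {
    r <- sp[[g]]
    sig <- r[r$p_adj < alpha, , drop = FALSE]
    region_dm <- vapply(c("Promoter", "UTR", "Body"), function(reg) {
      v <- sig$delta_m[sig$region == reg]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    data.frame(
      gene = g, min_adj_p = min(r$p_adj), n_probes = nrow(r),
      frac_significant = nrow(sig) / nrow(r),
      dM_All = if (nrow(sig)) mean(sig$delta_m) else NA_real_,
      dM_Promoter = region_dm[["Promoter"]],
      dM_UTR = region_dm[["UTR"]], dM_Body = region_dm[["Body"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$skewness <- skew$skewness[match(out$gene, skew$gene)]
  out <- out[order(out$min_adj_p, -out$frac_significant, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Select the top genes by differential-methylation significance
#'
#' @param summaries data.frame from [summarize_genes()] (already ordered).
#' @param n number of genes to keep (default 500); if fewer are available,
#'   all are returned with a warning.
#' @return the first `n` rows of `summaries`.
#' @export
select_top_genes <- function(summaries, n = 500) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(summaries) < n) {
    warning("only ", nrow(summaries), " genes available (requested ", n, ")")
    return(summaries)
  }
  summaries[seq_len(n), , drop = FALSE]
}

quadrant_of <- function(s, dm) {
  ifelse(s < 0 & dm > 0, "S<0,dM>0",
  ifelse(s > 0 & dm > 0, "S>0,dM>0",
  ifelse(s < 0 & dm < 0, "S<0,dM<0", "S>0,dM<0")))
}

#' Quadrant analysis of skewness versus differential methylation
#'
#' Splits the selected genes into quadrants by the signs of (S_g, dM) for
#' each probe region and tests, for every region pair and every
#' quadrant-vs-rest 2x2 table, whether the quadrant occupancy differs between
#' regions (two-sided Fisher's exact test). Genes with an exact zero in
#' either coordinate are excluded from quadrants and counted separately.
#'
#' @param top data.frame from [select_top_genes()].
#' @param regions regions to analyse (default All, Promoter, UTR, Body);
#'   regions with no genes are dropped with a warning.
#' @return list with `counts` (region x quadrant data.frame, plus n_boundary)
#'   and `tests` (region_a, region_b, quadrant, p).
#' @export
quadrant_analysis <- function(top, regions = c("All", "Promoter", "UTR", "Body")) {
  quads <- c("S<0,dM>0", "S>0,dM>0", "S<0,dM<0", "S>0,dM<0")
  counts <- list()
  for (reg in regions) {
    dm <- top[[paste0("dM_", reg)]]
    ok <- !is.na(dm) & !is.na(top$skewness)
    boundary <- ok & (dm == 0 | top$skewness == 0)
    use <- ok & !boundary
    if (!any(use)) {
      warning("region ", reg, " has no usable genes; excluded")
      next
    }
    q <- factor(quadrant_of(top$skewness[use], dm[use]), levels = quads)
    counts[[reg]] <- c(table(q), n_boundary = sum(boundary))
  }
  if (length(counts) == 0) stop("no region with usable genes")
  cm <- do.call(rbind, counts)
  tests <- list()
  regs <- rownames(cm)
  if (length(regs) >= 2) {
    for (i in seq_len(length(regs) - 1)) for (j in (i + 1):length(regs)) {
      for (q in quads) {
        a <- cm[regs[i], q]
        b <- sum(cm[regs[i], quads]) - a
        c_ <- cm[regs[j], q]
        d <- sum(cm[regs[j], quads]) - c_
        p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
        tests[[length(tests) + 1]] <- data.frame(
          region_a = regs[i], region_b = regs[j], quadrant = q, p = p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(
    counts = data.frame(region = rownames(cm), cm, check.names = FALSE,
                        row.names = NULL),
    tests = if (length(tests)) do.call(rbind, tests) else NULL
  )
}

#' Pearson correlation between skewness and differential methylation
#'
#' Correlation of (S_g, dM_region) over the selected genes with a 95%
#' confidence interval from the Fisher z transform:
#' tanh(atanh(r) +/- z_crit / sqrt(N - 3)).
#'
#' @param top data.frame from [select_top_genes()].
#' @param region one of "All", "Promoter", "UTR", "Body".
#' @param conf confidence level (default 0.95).
#' @return data.frame with region, n, r, ci_lo, ci_hi, degenerate (TRUE when
#'   |r| = 1 and the interval collapses).
#' @export
correlation_with_ci <- function(top, region = "Promoter", conf = 0.95) {
  dm <- top[[paste0("dM_", region)]]
  if (is.null(dm)) stop("unknown region: ", region)
  ok <- !is.na(dm) & !is.na(top$skewness)
  s <- top$skewness[ok]
  dm <- dm[ok]
  if (length(s) < 4) stop("need at least 4 genes with defined (S, dM)")
  if (stats::sd(s) == 0 || stats::sd(dm) == 0) {
    stop("zero variance in skewness or dM; correlation undefined")
  }
  r <- stats::cor(s, dm)
  n <- length(s)
  if (abs(r) >= 1 - 1e-15) {
    return(data.frame(region = region, n = n, r = r, ci_lo = r, ci_hi = r,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
  data.frame(region = region, n = n, r = r, ci_lo = ci[1], ci_hi = ci[2],
             degenerate = FALSE, stringsAsFactors = FALSE)
}

# centered rolling mean with shrinking windows at the edges
roll_mean <- function(x, window) {
  if (window <= 1) return(x)
  h <- (window - 1) %/% 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - h):min(length(x), i + h)], na.rm = TRUE)
  }, numeric(1))
}

#' Robustness of the correlation to the number of genes included
#'
#' Recomputes [correlation_with_ci()] at each N in a grid of top-gene counts,
#' per region, optionally smoothing the r series with a centered rolling
#' mean. Grid points beyond the available genes are truncated.
#'
#' @param summaries data.frame from [summarize_genes()].
#' @param n_grid top-gene counts (default seq(100, 500, by = 25)).
#' @param regions regions to sweep (default all four).
#' @param smooth_window rolling-mean window on the r series (default 1 = no
#'   smoothing; the analysis default presentation uses 3).
#' @return data.frame with columns region, n_top, n, r, r_smooth, ci_lo,
#'   ci_hi.
#' @export
robustness_sweep <- function(summaries, n_grid = seq(100, 500, by = 25),
                             regions = c("All", "Promoter", "UTR", "Body"),
                             smooth_window = 1) {
  n_grid <- sort(unique(pmin(n_grid, nrow(summaries))))
  rows <- list()
  for (reg in regions) {
    res <- lapply(n_grid, function(nn) {
      top <- select_top_genes(summaries, nn)
      tryCatch(correlation_with_ci(top, reg),
               error = function(e) data.frame(
                 region = reg, n = NA_integer_, r = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, degenerate = NA,
                 stringsAsFactors = FALSE))
    })
    res <- do.call(rbind, res)
    res$n_top <- n_grid
    res$r_smooth <- roll_mean(res$r, smooth_window)
    rows[[reg]] <- res[, c("region", "n_top", "n", "r", "r_smooth",
                           "ci_lo", "ci_hi")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shared and cohort-unique significant genes across cohorts
#'
#' The shared set is the intersection of all cohorts' significant-gene lists;
#' each cohort then contributes its top `n_unique` genes (in its own summary
#' order) outside the shared set — the construction used to compare equal
#' numbers of cohort-specific genes side by side.
#'
#' @param sig_sets named list (>= 2 cohorts) of character vectors of
#'   significant genes, each ordered by significance.
#' @param n_unique unique genes to keep per cohort; if fewer are available,
#'   all are kept with a warning.
#' @return list with `shared` and `unique` (named list per cohort).
#' @export
intersect_and_unique <- function(sig_sets, n_unique) {
  if (length(sig_sets) < 2) stop("need at least 2 cohorts")
  shared <- Reduce(intersect, sig_sets)
  uniq <- lapply(names(sig_sets), function(nm) {
    u <- setdiff(sig_sets[[nm]], shared)
    if (length(u) < n_unique) {
      warning("cohort ", nm, ": only ", length(u), " unique genes available")
      u
    } else {
      u[seq_len(n_unique)]
    }
  })
  names(uniq) <- names(sig_sets)
  list(shared = shared, unique = uniq)
}
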