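#' Signed real cube root
#'
#' Returns sign(x) * |x|^(1/3), the real cube root. Used so that the skewness
#' statistic preserves the sign of the third central moment and is continuous
#' through zero.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
signed_cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Skewness of a single numeric vector
#'
#' The cohort skewness statistic: the signed cube root of the third central
#' moment (with an n-1 denominator) divided by the sample standard deviation,
#'
#'   S = cbrt( (1/(n-1)) * sum((x - mean(x))^3) ) / sd(x).
#'
#' The statistic is invariant under positive affine transforms a*x + c (a > 0)
#' and antisymmetric under sign flip. With `unbiased = TRUE` the third central
#' moment is multiplied by the correction factor n/(n-2) before the cube root.
#'
#' @param x numeric vector, length >= 3, finite values.
#' @param unbiased logical; apply the n/(n-2) bias correction to the third
#'   moment (default FALSE).
#' @return a single numeric value, or NA_real_ if the vector has zero variance.
#' @examples
#' skewness_stat(c(0, 0, 3))            # ~0.8327
#' skewness_stat(c(0, 0, 3), TRUE)      # ~1.2009
#' @export
skewness_stat <- function(x, unbiased = FALSE) {
  if (length(x) < 3) stop("skewness requires at least 3 observations")
  if (!all(is.finite(x))) stop("skewness requires finite values")
  n <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  m3 <- sum((x - mu)^3) / (n - 1)
  if (unbiased) m3 <- m3 * n / (n - 2)
  signed_cbrt(m3) / s
}

#' Per-gene skewness table for an expression matrix
#'
#' Computes the skewness statistic for every row (gene) of a gene x sample
#' log2-expression matrix, together with the moments used. Genes with zero
#' variance get an undefined (NA) skewness and are excluded from downstream
#' splits; their count is reported via the "n_zero_variance" attribute.
#'
#' @param x numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns. At least 3 columns.
#' @param unbiased logical; apply the n/(n-2) third-moment correction.
#' @return data.frame with columns gene, skewness, mean, sd, n and attributes
#'   `unbiased` and `n_zero_variance`.
#' @export
compute_skewness <- function(x, unbiased = FALSE) {
  x <- validate_matrix(x, "expression")
  if (ncol(x) < 3) stop("skewness requires at least 3 samples")
  n <- ncol(x)
  mu <- rowMeans(x)
  cx <- x - mu
  m2 <- rowSums(cx^2) / (n - 1)
  m3 <- rowSums(cx^3) / (n - 1)
  if (unbiased) m3 <- m3 * n / (n - 2)
  sdev <- sqrt(m2)
  S <- ifelse(sdev > 0, signed_cbrt(m3) / sdev, NA_real_)
  out <- data.frame(
    gene = rownames(x), skewness = S, mean = mu, sd = sdev, n = n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "unbiased") <- unbiased
  attr(out, "n_zero_variance") <- sum(sdev == 0)
  out
}

#' Relative magnitude of the small-sample skewness correction
#'
#' The multiplicative change that the n/(n-2) third-moment correction induces
#' on the skewness statistic itself: (n/(n-2))^(1/3) - 1. At n = 500 this is
#' about 0.13%, i.e. negligible for large cohorts.
#'
#' @param n number of samples, must exceed 2.
#' @return the proportion by which the corrected statistic exceeds the biased
#'   one (e.g. 0.00134 at n = 500).
#' @export
correction_magnitude <- function(n) {
  if (any(n <= 2)) stop("correction factor requires n > 2")
  (n / (n - 2))^(1 / 3) - 1
}

#' Gene splitting: fraction of genes with negative skewness
#'
#' The gene split of a cohort is the fraction of genes whose expression
#' distribution is negatively skewed. Genes with exactly zero skewness count
#' as positive by default (few genes have exactly symmetric expression);
#' genes with undefined skewness are excluded.
#'
#' @param skew data.frame from [compute_skewness()].
#' @param zero_as_positive logical; count S = 0 genes as positively skewed
#'   (default TRUE).
#' @return data.frame with one row: fraction_negative, fraction_positive,
#'   n_genes (number of genes with defined skewness).
#' @export
gene_split <- function(skew, zero_as_positive = TRUE) {
  s <- skew$skewness[!is.na(skew$skewness)]
  if (length(s) == 0) stop("no genes with defined skewness")
  neg <- if (zero_as_positive) sum(s < 0) else sum(s <= 0)
  data.frame(
    fraction_negative = neg / length(s),
    fraction_positive = 1 - neg / length(s),
    n_genes = length(s)
  )
}

#' Skew difference between two cohorts
#'
#' For every gene present in both skewness tables, the signed difference
#' S(first) - S(second). By convention a positive skew difference means the
#' gene is more positively skewed in the first-named cohort.
#'
#' @param first,second data.frames from [compute_skewness()].
#' @return data.frame with columns gene, skew_first, skew_second, delta_skew;
#'   attributes `first` and `second` carry optional cohort names.
#' @param first_name,second_name optional cohort labels stored as attributes.
#' @export
skew_difference <- function(first, second,
                            first_name = "first", second_name = "second") {
  common <- intersect(first$gene, second$gene)
  if (length(common) == 0) stop("no genes shared between the two cohorts")
  i <- match(common, first$gene)
  j <- match(common, second$gene)
  out <- data.frame(
    gene = common,
    skew_first = first$skewness[i],
    skew_second = second$skewness[j],
    stringsAsFactors = FALSE
  )
  out$delta_skew <- out$skew_first - out$skew_second
  out <- out[!is.na(out$delta_skew), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "first") <- first_name
  attr(out, "second") <- second_name
  out
}

#' Compare two groups of gene splits across platforms
#'
#' Welch's unequal-variance t-test on the fraction_negative values of two
#' groups of cohorts (e.g. microarray vs RNA-seq), with per-group Shapiro-Wilk
#' normality checks supporting the t-test's normality assumption.
#'
#' @param splits_a,splits_b data.frames whose rows are [gene_split()] results
#'   (or numeric vectors of negative-split fractions); each group needs >= 3
#'   entries.
#' @return list with fields t_statistic, p_value, df, shapiro_p_a, shapiro_p_b,
#'   mean_a, mean_b. Degenerate zero-variance groups yield t = 0, p = 1
#'   ("no evidence" rather than an error).
#' @export
compare_splits <- function(splits_a, splits_b) {
  a <- if (is.data.frame(splits_a)) splits_a$fraction_negative else as.numeric(splits_a)
  b <- if (is.data.frame(splits_b)) splits_b$fraction_negative else as.numeric(splits_b)
  if (length(a) < 3 || length(b) < 3) stop("each group needs at least 3 gene splits")
  sw_a <- if (stats::sd(a) > 0) stats::shapiro.test(a)$p.value else NA_real_
  sw_b <- if (stats::sd(b) > 0) stats::shapiro.test(b)$p.value else NA_real_
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1, parameter = c(df = NA_real_))
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  list(
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    df = unname(tt$parameter),
    shapiro_p_a = sw_a, shapiro_p_b = sw_b,
    mean_a = mean(a), mean_b = mean(b)
  )
}

#' Convert FPKM to TPM
#'
#' Per sample, TPM_g = FPKM_g / sum_g(FPKM_g) * 1e6, computed on the linear
#' scale. When the input is log2-transformed the matrix is unlogged, converted
#' and relogged (log2(TPM + offset) with the same offset convention as the
#' input: plain log2 here, offset 0).
#'
#' @param x numeric matrix of FPKM values (genes x samples), or log2(FPKM) if
#'   `input_is_log2`.
#' @param input_is_log2 logical; unlog before conversion and relog after.
#' @return matrix of the same shape in TPM (or log2 TPM) units.
#' @export
fpkm_to_tpm <- function(x, input_is_log2 = FALSE) {
  x <- validate_matrix(x, "expression")
  lin <- if (input_is_log2) 2^x else x
  if (any(lin < 0)) stop("FPKM values must be non-negative")
  tot <- colSums(lin)
  if (any(tot == 0)) {
    stop("sample(s) with zero total FPKM: ",
         paste(colnames(lin)[tot == 0], collapse = ", "))
  }
  tpm <- sweep(lin, 2, tot, "/") * 1e6
  if (input_is_log2) log2(tpm) else tpm
}

#' Skewness versus mean-expression diagnostic
#'
#' Bins genes by mean expression and reports the Pearson correlation between
#' mean and skewness within each bin, plus the global correlation. A designed
#' property of the statistic is shift/scale invariance, so for most of the
#' expression spectrum the correlation should be minimal.
#'
#' @param skew data.frame from [compute_skewness()].
#' @param n_bins number of equal-count mean-expression bins (default 10).
#' @return data.frame with columns bin, mean_lo, mean_hi, n, r; attribute
#'   `overall_r` holds the global correlation. Bins where the correlation is
#'   undefined (constant skewness or < 2 genes) report NA.
#' @export
skew_vs_mean_diagnostic <- function(skew, n_bins = 10) {
  ok <- !is.na(skew$skewness)
  mu <- skew$mean[ok]
  s <- skew$skewness[ok]
  if (length(s) < 2) stop("need at least 2 genes with defined skewness")
  if (n_bins < 1) stop("n_bins must be >= 1")
  overall <- if (stats::sd(s) > 0 && stats::sd(mu) > 0) stats::cor(mu, s) else NA_real_
  if (n_bins == 1) {
    br <- range(mu)
    idx <- rep(1L, length(mu))
  } else {
    br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) {
      warning("mean-expression bins collapsed; reporting a single bin")
      br <- range(mu)
      idx <- rep(1L, length(mu))
    } else {
      idx <- as.integer(cut(mu, breaks = br, include.lowest = TRUE))
    }
  }
  bins <- sort(unique(idx))
  out <- do.call(rbind, lapply(bins, function(b) {
    m <- idx == b
    r <- if (sum(m) >= 2 && stats::sd(s[m]) > 0 && stats::sd(mu[m]) > 0) {
      stats::cor(mu[m], s[m])
    } else NA_real_
    data.frame(bin = b, mean_lo = min(mu[m]), mean_hi = max(mu[m]),
               n = sum(m), r = r)
  }))
  attr(out, "overall_r") <- overall
  out
}
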