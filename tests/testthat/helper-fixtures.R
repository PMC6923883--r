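# Shared in-code fixtures for the test suite.

# independent re-statement of the skewness formula used as the brute-force
# oracle: every quantity spelled out, no shared helpers
oracle_skewness <- function(x, unbiased = FALSE) {
  n <- length(x)
  mu <- sum(x) / n
  m3 <- sum((x - mu)^3) / (n - 1)
  if (unbiased) m3 <- m3 * n / (n - 2)
  s2 <- sum((x - mu)^2) / (n - 1)
  root <- if (m3 < 0) -((-m3)^(1 / 3)) else m3^(1 / 3)
  root / sqrt(s2)
}

# small deterministic expression matrix
small_expr <- function(n_genes = 20, n_samples = 30, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, 1), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# moderate linked cohort reused by the methylation-link tests
linked_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_genes = 400, n_samples = 300,
                           tail_fraction = 0.1, linked_fraction = 0.25,
                           target_corr = -0.8, seed = 2024)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})

# exhaustive null distribution of the Mann-Whitney U statistic for group
# sizes (m, n) over distinct values, by enumerating every assignment of
# ranks to the first group
ranksum_null_U <- function(m, n) {
  combos <- utils::combn(m + n, m)
  apply(combos, 2, function(idx) sum(idx) - m * (m + 1) / 2)
}

# two-sided exact rank-sum p by enumeration
oracle_ranksum_p <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  m <- length(a)
  u_obs <- sum(rank(c(a, b))[seq_len(m)]) - m * (m + 1) / 2
  u_all <- ranksum_null_U(m, length(b))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# upper-tail hypergeometric probability from exact binomial coefficients
oracle_hyper_upper <- function(k, k_set, m, n_u) {
  hi <- min(k_set, m)
  if (k > hi) return(0)
  i <- max(k, 0):hi
  sum(choose(k_set, i) * choose(n_u - k_set, m - i)) / choose(n_u, m)
}

# two-sided Fisher exact p for a 2x2 table by enumerating the conditional
# hypergeometric support (the standard sum-of-smaller-pmf rule)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  pmf <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  p_obs <- pmf[support == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-07)])
}
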