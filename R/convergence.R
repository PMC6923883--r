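# Sample-size sensitivity of the gene split: subsample cohorts at increasing
# sizes and fit an exponential convergence model s_n = a * exp(-b n) + L.
# The limit L approximates the full-population split and exp(-b) is the rate
# of convergence; the nth relative error is (s_n - L) / L.

#' Gene splits on random subsamples of a cohort
#'
#' For each requested size, draws `repeats` subsets of samples without
#' replacement, computes the gene split on each, and records the mean and
#' dispersion of the negative-skew fraction.
#'
#' @param x gene x sample expression matrix.
#' @param sizes sample sizes (each >= 3, <= ncol(x)); defaults to 10
#'   log-spaced sizes from 20 to the cohort size.
#' @param repeats subsets drawn per size (default 25).
#' @param seed optional integer seed.
#' @param unbiased passed to [compute_skewness()].
#' @return data.frame with columns size, split (mean fraction negative),
#'   split_sd, repeats.
#' @export
subsample_splits <- function(x, sizes = NULL, repeats = 25, seed = NULL,
                             unbiased = FALSE) {
  x <- validate_matrix(x, "expression")
  if (is.null(sizes)) {
    lo <- min(20, ncol(x))
    sizes <- unique(round(exp(seq(log(lo), log(ncol(x)), length.out = 10))))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 3)) stop("subsample sizes must be >= 3")
  if (max(sizes) > ncol(x)) stop("subsample size exceeds the cohort size")
  if (repeats < 1) stop("repeats must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    fr <- vapply(seq_len(repeats), function(i) {
      idx <- if (sz == ncol(x)) seq_len(ncol(x)) else sample.int(ncol(x), sz)
      gene_split(compute_skewness(x[, idx, drop = FALSE], unbiased))$fraction_negative
    }, numeric(1))
    data.frame(size = sz, split = mean(fr), split_sd = stats::sd(fr),
               repeats = repeats)
  })
  do.call(rbind, rows)
}

#' Fit the exponential convergence model to a gene-split series
#'
#' Least-squares fit of s_n = a * exp(-b * n) + L with b constrained positive,
#' via Levenberg-Marquardt with multi-start initialization: L starts at the
#' last observed split, b from an ordinary regression of log|s_n - L0| on n,
#' a from its intercept, plus jittered restarts against local minima.
#'
#' @param series data.frame with columns size and split (e.g. from
#'   [subsample_splits()] or [generate_convergence_series()]).
#' @param n_starts number of jittered initializations (default 6).
#' @return list of class "convergence_fit": a, b, L, C = exp(-b), errors
#'   E_n = (s_n - L)/L (NA when |L| < 1e-8), final_abs_pct_error = |E_last|*100,
#'   fitted values, rss, converged flag and diagnostics. A constant series
#'   short-circuits to a = 0, L = the constant, all errors 0.
#' @export
fit_convergence <- function(series, n_starts = 6) {
  if (!all(c("size", "split") %in% names(series))) {
    stop("series needs columns size and split")
  }
  n <- series$size
  s <- series$split
  if (length(n) < 4) stop("need at least 4 points to fit the convergence model")
  ord <- order(n)
  n <- n[ord]
  s <- s[ord]
  if (stats::sd(s) < 1e-12) {
    L <- mean(s)
    return(structure(list(
      a = 0, b = NA_real_, L = L, C = NA_real_,
      errors = rep(0, length(n)), final_abs_pct_error = 0,
      fitted = rep(L, length(n)), rss = 0, converged = TRUE,
      sizes = n, observed = s, diagnostics = "constant series"
    ), class = "convergence_fit"))
  }

  L0 <- s[length(s)]
  r0 <- s - L0
  use <- abs(r0) > 1e-12
  if (sum(use) >= 2) {
    co <- unname(stats::coef(stats::lm(log(abs(r0[use])) ~ n[use])))
    b0 <- max(-co[2], 1e-4)
    a0 <- sign(r0[which(use)[1]]) * exp(co[1])
  } else {
    b0 <- 1 / max(n)
    a0 <- s[1] - L0
  }

  # deterministic fixed jitter grid rather than random restarts
  best <- NULL
  msgs <- character(0)
  jit <- cbind(a = c(1, 0.5, 2, 1, 1, 0.25), b = c(1, 1, 1, 0.3, 3, 1))
  for (i in seq_len(min(n_starts, nrow(jit)))) {
    st <- list(a = unname(a0 * jit[i, "a"]), b = unname(b0 * jit[i, "b"]),
               L = unname(L0))
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ a * exp(-b * n) + L, start = st,
                        lower = c(a = -Inf, b = 1e-8, L = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      msgs <- c(msgs, conditionMessage(fit))
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(
      a = NA_real_, b = NA_real_, L = NA_real_, C = NA_real_,
      errors = rep(NA_real_, length(n)), final_abs_pct_error = NA_real_,
      fitted = rep(NA_real_, length(n)), rss = NA_real_, converged = FALSE,
      sizes = n, observed = s, diagnostics = unique(msgs)
    ), class = "convergence_fit"))
  }
  cf <- stats::coef(best$fit)
  L <- unname(cf["L"])
  errors <- if (abs(L) < 1e-8) rep(NA_real_, length(n)) else (s - L) / L
  structure(list(
    a = unname(cf["a"]), b = unname(cf["b"]), L = L,
    C = exp(-unname(cf["b"])),
    errors = errors,
    final_abs_pct_error = if (all(is.na(errors))) NA_real_ else
      abs(errors[length(errors)]) * 100,
    fitted = unname(stats::fitted(best$fit)), rss = best$rss,
    converged = TRUE, sizes = n, observed = s, diagnostics = character(0)
  ), class = "convergence_fit")
}
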