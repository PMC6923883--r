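# Categorize cross-cohort skew differences with a univariate variable-variance
# Gaussian mixture. EM is fit for each candidate number of components K, the
# BIC (2 logL - p log n, p = 3K - 1 free parameters, larger is better) selects
# K over 1..10, and components ordered by mean map to the three categories
# "<" (shift toward negative skew), "~" (negligible change), ">" (shift toward
# positive skew).

row_log_sum_exp <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  mx <- m[, 1]
  for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# k-means++-style seeding: first center uniform, subsequent centers sampled
# with probability proportional to squared distance from the nearest chosen
# center.
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  d2 <- (x - centers[1])^2
  if (k > 1) {
    for (j in 2:k) {
      centers[j] <- if (sum(d2) == 0) x[sample.int(length(x), 1)] else
        x[sample.int(length(x), 1, prob = d2)]
      d2 <- pmin(d2, (x - centers[j])^2)
    }
  }
  centers
}

# initial parameters from a k-means++ seeding and nearest-centre assignment
em_init_params <- function(x, k) {
  n <- length(x)
  centers <- kmeanspp_centers(x, k)
  assign0 <- apply(abs(outer(x, centers, "-")), 1, which.min)
  w <- tabulate(assign0, k) / n
  w[w == 0] <- 1 / n
  w <- w / sum(w)
  mu <- vapply(seq_len(k), function(j) {
    if (any(assign0 == j)) mean(x[assign0 == j]) else centers[j]
  }, numeric(1))
  v <- vapply(seq_len(k), function(j) {
    if (sum(assign0 == j) > 1) stats::var(x[assign0 == j]) else stats::var(x)
  }, numeric(1))
  list(weights = w, means = mu, variances = v)
}

em_gmm1d_once <- function(x, k, tol = 1e-6, max_iter = 500,
                          var_floor = 1e-6 * stats::var(x), init = NULL) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x)
    v <- max(stats::var(x) * (n - 1) / n, var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(list(weights = 1, means = mu, variances = v, loglik = ll,
                iterations = 0L, ll_trace = ll))
  }
  if (is.null(init)) init <- em_init_params(x, k)
  w <- init$weights
  mu <- init$means
  v <- pmax(init$variances, var_floor)

  logdens <- matrix(0, n, k)
  halfl2pi <- 0.5 * log(2 * pi)
  ll_old <- -Inf
  ll_trace <- numeric(max_iter)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      logdens[, j] <- log(w[j]) - halfl2pi - 0.5 * log(v[j]) -
        (x - mu[j])^2 / (2 * v[j])
    }
    lse <- row_log_sum_exp(logdens)
    ll <- sum(lse)
    ll_trace[it] <- ll
    resp <- exp(logdens - lse)
    nk <- pmax(colSums(resp), 1e-300)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    for (j in seq_len(k)) v[j] <- sum(resp[, j] * (x - mu[j])^2) / nk[j]
    v <- pmax(v, var_floor)
    if (is.finite(ll_old) && (ll - ll_old) <= tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = w, means = mu, variances = v, loglik = ll,
       iterations = it, ll_trace = ll_trace[seq_len(it)])
}

#' Fit variable-variance Gaussian mixtures to skew differences
#'
#' EM with k-means++-style initialization and multiple restarts is run for
#' each candidate K; the K maximizing BIC = 2 logL - (3K - 1) log(n) is
#' selected.
#'
#' @param diffs data.frame from [skew_difference()] (column delta_skew), or a
#'   plain numeric vector; needs >= 20 values.
#' @param k_min,k_max candidate component range (defaults 1 and 10).
#' @param seed optional integer seed for reproducible restarts.
#' @param n_restarts EM restarts per K (default 10; K = 1 is closed form).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter EM iteration cap per restart (default 500).
#' @return list of class "skew_mixture_fit": per-K data.frame `model_table`
#'   (k, loglik, n_params, bic), `selected_k`, per-K parameter list `fits`,
#'   the data and gene ids.
#' @export
fit_skew_mixture <- function(diffs, k_min = 1, k_max = 10, seed = NULL,
                             n_restarts = 10, tol = 1e-6, max_iter = 500) {
  x <- if (is.data.frame(diffs)) diffs$delta_skew else as.numeric(diffs)
  genes <- if (is.data.frame(diffs)) diffs$gene else
    sprintf("obs%05d", seq_along(x))
  keep <- is.finite(x)
  x <- x[keep]
  genes <- genes[keep]
  if (length(x) < 20) stop("need at least 20 finite skew differences")
  if (k_min < 1 || k_max < k_min) stop("invalid component range")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  var_floor <- 1e-6 * stats::var(x)

  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  names(fits) <- as.character(ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    reps <- if (k == 1) 1 else n_restarts
    # each restart gets a short EM burn-in; only the best is polished to
    # full tolerance — the standard economy for multi-start EM
    best <- NULL
    for (r in seq_len(reps)) {
      f <- em_gmm1d_once(x, k, tol = 1e-4, max_iter = min(50, max_iter),
                         var_floor = var_floor)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    if (k > 1) {
      best <- em_gmm1d_once(x, k, tol = tol, max_iter = max_iter,
                            var_floor = var_floor,
                            init = best[c("weights", "means", "variances")])
    }
    best$n_params <- 3 * k - 1
    best$bic <- 2 * best$loglik - best$n_params * log(n)
    fits[[i]] <- best
  }
  tab <- data.frame(
    k = ks,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    bic = vapply(fits, `[[`, numeric(1), "bic")
  )
  structure(list(
    model_table = tab,
    selected_k = ks[which.max(tab$bic)],
    fits = fits, x = x, genes = genes
  ), class = "skew_mixture_fit")
}

# posterior responsibilities under stored parameters
mixture_posterior <- function(fit_k, x) {
  k <- length(fit_k$means)
  logdens <- vapply(seq_len(k), function(j) {
    log(fit_k$weights[j]) +
      stats::dnorm(x, fit_k$means[j], sqrt(fit_k$variances[j]), log = TRUE)
  }, numeric(length(x)))
  logdens <- matrix(logdens, nrow = length(x))
  exp(logdens - row_log_sum_exp(logdens))
}

#' Assign genes to skew-difference categories
#'
#' Orders the fitted components by mean and maps them onto the three
#' categories: the lowest-mean component is "<" (more negative skew in the
#' first cohort), the highest-mean is ">", anything between is "~". Each gene
#' goes to the category of its maximum-posterior component. With
#' `force_k3 = TRUE` (the default pipeline behaviour) the K = 3 fit is used
#' regardless of the BIC winner; otherwise the selected K is used and, when
#' K < 3, only the representable categories are emitted with a warning.
#'
#' @param fit a "skew_mixture_fit" from [fit_skew_mixture()].
#' @param force_k3 use the K = 3 fit regardless of BIC (default TRUE).
#' @return data.frame with columns gene, delta_skew, component, category;
#'   attributes `category_map` (component mean -> category) and `k`.
#' @export
assign_categories <- function(fit, force_k3 = TRUE) {
  stopifnot(inherits(fit, "skew_mixture_fit"))
  k_use <- if (force_k3) 3L else fit$selected_k
  fk <- fit$fits[[as.character(k_use)]]
  if (is.null(fk)) stop("no fitted model with K = ", k_use)
  ord <- order(fk$means)
  cats <- if (k_use >= 3) {
    c("<", rep("~", k_use - 2), ">")
  } else if (k_use == 2) {
    warning("only 2 components fitted; emitting categories '<' and '>'")
    c("<", ">")
  } else {
    warning("single component fitted; all genes categorized '~'")
    "~"
  }
  category_of_component <- character(k_use)
  category_of_component[ord] <- cats
  post <- mixture_posterior(fk, fit$x)
  comp <- max.col(post, ties.method = "first")
  out <- data.frame(
    gene = fit$genes, delta_skew = fit$x,
    component = comp, category = category_of_component[comp],
    stringsAsFactors = FALSE
  )
  attr(out, "category_map") <- stats::setNames(category_of_component,
                                               sprintf("%.4f", fk$means))
  attr(out, "k") <- k_use
  out
}
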