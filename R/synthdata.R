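# Synthetic cohorts with planted expression asymmetry and a matched
# methylation link. Each gene's expression is a two-component location-shift
# model: a main Normal(baseline_mean, baseline_sd^2) population and a minority
# "tail" subgroup of fraction pi shifted by delta in the planted direction.
# For "linked" genes the same tail patients also carry region-specific
# M-value shifts, so expression asymmetry and differential methylation share
# a patient-level cause.

#' Population moments of the two-component tail model
#'
#' For a mixture (1-pi) N(0, sigma^2) + pi N(delta, sigma^2), the variance is
#' sigma^2 + pi(1-pi) delta^2 and the third central moment is
#' pi(1-pi)(1-2pi) delta^3; the planted population skewness follows as the
#' signed cube root of the third moment over the standard deviation.
#'
#' @param delta tail shift (log2 units, signed).
#' @param pi_tail tail fraction in [0, 0.5).
#' @param sigma within-component standard deviation.
#' @return named vector with variance, third_moment, skewness.
#' @export
planted_moments <- function(delta, pi_tail, sigma = 1) {
  v <- sigma^2 + pi_tail * (1 - pi_tail) * delta^2
  m3 <- pi_tail * (1 - pi_tail) * (1 - 2 * pi_tail) * delta^3
  c(variance = v, third_moment = m3, skewness = signed_cbrt(m3) / sqrt(v))
}

#' Tail shift giving a requested planted skewness
#'
#' Inverts the population skewness of the two-component model in `delta` for
#' fixed tail fraction and scale. The skewness saturates as delta grows, so a
#' target beyond the asymptote is an error.
#'
#' @param target positive target skewness magnitude.
#' @param pi_tail tail fraction in (0, 0.5).
#' @param sigma within-component standard deviation.
#' @return the positive delta whose planted skewness equals `target`.
#' @export
delta_for_skewness <- function(target, pi_tail, sigma = 1) {
  if (target <= 0) stop("target skewness must be positive")
  s_max <- planted_moments(1e6 * sigma, pi_tail, sigma)[["skewness"]]
  if (target >= s_max) {
    stop(sprintf("target skewness %.3f exceeds the asymptote %.3f at pi = %.3f",
                 target, s_max, pi_tail))
  }
  f <- function(d) planted_moments(d, pi_tail, sigma)[["skewness"]] - target
  stats::uniroot(f, lower = 0, upper = 100 * sigma, tol = 1e-10)$root
}

#' Configuration for a synthetic cohort
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param tail_fraction per-gene tail fraction pi in [0, 0.5).
#' @param tail_shift expression shift delta (log2 units) applied to tail
#'   samples of unlinked planted-skew genes; 0 disables planted skew.
#' @param baseline_mean,baseline_sd log2-expression location and scale of the
#'   main component.
#' @param baseline_mean_sd between-gene spread of the baseline mean (default
#'   0: all genes share one baseline; a few log2 units is typical of real
#'   cohorts, and the skewness statistic is invariant to it either way).
#' @param fraction_negative_skew proportion of planted-skew genes whose tail
#'   lies on the left.
#' @param n_probes_per_gene methylation probes simulated per gene.
#' @param region_probabilities named probabilities over Promoter/UTR/Body;
#'   must sum to 1.
#' @param methyl_shift named per-region base M-value shift magnitudes applied
#'   to tail patients of linked genes; the orientation relative to the skew
#'   direction is set by the sign of `target_corr` (negative: shifts oppose
#'   the skew direction, the default regime).
#' @param methyl_noise_sd per-sample M-value noise standard deviation.
#' @param linked_fraction proportion of genes given a planted methylation
#'   link.
#' @param target_corr planted correlation between skewness and linked-region
#'   differential methylation across linked genes (negative by default).
#' @param linked_skew_range magnitude range of the planted skewness drawn
#'   uniformly for linked genes; must stay below the model asymptote at
#'   `tail_fraction`.
#' @param magnitude_floor fraction of the base shift magnitude every linked
#'   gene is guaranteed, keeping all linked genes detectable; the remaining
#'   spread is lognormal with dispersion solved so the planted correlation is
#'   attained (see the methods vignette).
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return validated config list of class "cohort_config".
#' @export
cohort_config <- function(n_genes = 200, n_samples = 100,
                          tail_fraction = 0.1, tail_shift = 3,
                          baseline_mean = 8, baseline_sd = 1,
                          baseline_mean_sd = 0,
                          fraction_negative_skew = 0.5,
                          n_probes_per_gene = 5,
                          region_probabilities = c(Promoter = 0.4, UTR = 0.2, Body = 0.4),
                          methyl_shift = c(Promoter = -1, UTR = 0, Body = 0),
                          methyl_noise_sd = 0.3,
                          linked_fraction = 0, target_corr = -0.8,
                          linked_skew_range = c(0.8, 1.25),
                          magnitude_floor = 0.35,
                          seed = 1L) {
  stopifnot(length(n_genes) == 1, length(n_samples) == 1)
  if (n_genes < 1 || n_samples < 3 || n_genes != round(n_genes) ||
      n_samples != round(n_samples)) {
    stop("n_genes and n_samples must be positive integers (n_samples >= 3)")
  }
  if (tail_fraction < 0 || tail_fraction >= 0.5) stop("tail_fraction must lie in [0, 0.5)")
  if (fraction_negative_skew < 0 || fraction_negative_skew > 1) {
    stop("fraction_negative_skew must lie in [0, 1]")
  }
  if (n_probes_per_gene < 1 || n_probes_per_gene != round(n_probes_per_gene)) {
    stop("n_probes_per_gene must be a positive integer")
  }
  regs <- c("Promoter", "UTR", "Body")
  if (!setequal(names(region_probabilities), regs)) {
    stop("region_probabilities must be named Promoter, UTR, Body")
  }
  region_probabilities <- region_probabilities[regs]
  if (abs(sum(region_probabilities) - 1) > 1e-8) {
    stop("region_probabilities must sum to 1")
  }
  if (!setequal(names(methyl_shift), regs)) {
    stop("methyl_shift must be named Promoter, UTR, Body")
  }
  methyl_shift <- methyl_shift[regs]
  if (linked_fraction < 0 || linked_fraction > 1) stop("linked_fraction must lie in [0, 1]")
  if (abs(target_corr) >= 1) stop("target_corr must lie in (-1, 1)")
  if (baseline_sd <= 0 || methyl_noise_sd <= 0) stop("scales must be positive")
  if (baseline_mean_sd < 0) stop("baseline_mean_sd must be non-negative")
  if (length(linked_skew_range) != 2 || diff(linked_skew_range) < 0 ||
      linked_skew_range[1] <= 0) {
    stop("linked_skew_range must be an increasing positive pair")
  }
  if (magnitude_floor < 0 || magnitude_floor >= 1) stop("magnitude_floor must lie in [0, 1)")
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    tail_fraction = tail_fraction, tail_shift = tail_shift,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    baseline_mean_sd = baseline_mean_sd,
    fraction_negative_skew = fraction_negative_skew,
    n_probes_per_gene = as.integer(n_probes_per_gene),
    region_probabilities = region_probabilities,
    methyl_shift = methyl_shift, methyl_noise_sd = methyl_noise_sd,
    linked_fraction = linked_fraction, target_corr = target_corr,
    linked_skew_range = linked_skew_range,
    magnitude_floor = magnitude_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

# Lognormal dispersion making the planted skewness/methylation correlation hit
# target_corr. With balanced skew directions, shift sign opposite direction,
# and shift magnitude independent of skew magnitude within a direction, the
# population correlation is -1/sqrt((1+cv_s^2)(1+cv_m^2)), where cv_s and cv_m
# are the coefficients of variation of the two magnitudes; solve for cv_m.
linked_magnitude_cv <- function(target_corr, skew_range) {
  mu_s <- mean(skew_range)
  cv_s <- (diff(skew_range) / sqrt(12)) / mu_s
  rho2 <- target_corr^2
  cv2 <- 1 / (rho2 * (1 + cv_s^2)) - 1
  if (cv2 < 0) {
    stop("requested |target_corr| unattainable with the given linked_skew_range")
  }
  sqrt(cv2)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws an expression matrix, a matched methylation M-value matrix, a probe
#' annotation, a small gene-set collection and the planted truth. See the
#' methods vignette for the generative model and the construction of the
#' planted skewness/methylation correlation.
#'
#' @param config a [cohort_config()] object.
#' @return list of class "skew_cohort" with elements `expression` (gene x
#'   sample matrix), `methylation` (probe x sample M-values), `annotation`
#'   (probe_id, gene_id, region), `gene_sets` (named list with a `modules`
#'   attribute), `truth` (list: `genes` data.frame with planted direction,
#'   delta, planted skewness, linked flag and per-region shifts; `tails` named
#'   list of tail sample ids), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  ns <- config$n_samples
  genes <- sprintf("gene%04d", seq_len(ng))
  samples <- sprintf("sample%03d", seq_len(ns))
  pi_tail <- config$tail_fraction
  k_tail <- round(pi_tail * ns)
  sigma <- config$baseline_sd

  # planted directions; a gene with no tail (pi = 0 or delta = 0) is symmetric
  has_tail <- k_tail > 0 && config$tail_shift != 0
  direction <- if (has_tail) {
    ifelse(stats::runif(ng) < config$fraction_negative_skew, -1L, 1L)
  } else rep(0L, ng)

  n_linked <- round(config$linked_fraction * ng)
  linked <- rep(FALSE, ng)
  if (n_linked > 0) {
    if (!has_tail) stop("linked genes require a non-zero tail")
    linked[sample.int(ng, n_linked)] <- TRUE
  }

  # per-gene shift: fixed for unlinked genes, skewness-targeted for linked
  delta <- ifelse(direction != 0, abs(config$tail_shift), 0)
  planted_s <- vapply(delta, function(d) {
    planted_moments(d, pi_tail, sigma)[["skewness"]]
  }, numeric(1)) * ifelse(direction != 0, 1, 0)
  if (n_linked > 0) {
    sev <- stats::runif(n_linked, config$linked_skew_range[1],
                        config$linked_skew_range[2])
    delta[linked] <- vapply(sev, delta_for_skewness, numeric(1),
                            pi_tail = pi_tail, sigma = sigma)
    planted_s[linked] <- sev
  }
  planted_s <- planted_s * ifelse(direction < 0, -1, 1)

  # linked methylation magnitudes: floor + lognormal spread, dispersion solved
  # so that corr(planted skewness, shift) = target_corr across linked genes
  shift_scale <- rep(0, ng)
  if (n_linked > 0) {
    f0 <- config$magnitude_floor
    cv_m <- linked_magnitude_cv(config$target_corr, config$linked_skew_range)
    cv_x <- cv_m / (1 - f0)
    sdlog <- sqrt(log(1 + cv_x^2))
    xln <- stats::rlnorm(n_linked, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    shift_scale[linked] <- f0 + (1 - f0) * xln
  }
  link_sign <- if (config$target_corr < 0) -1 else 1

  # expression + per-gene tail draws (independent across genes)
  gene_baseline <- config$baseline_mean +
    if (config$baseline_mean_sd > 0) {
      stats::rnorm(ng, 0, config$baseline_mean_sd)
    } else rep(0, ng)
  expr <- matrix(stats::rnorm(ng * ns, 0, sigma),
                 nrow = ng, dimnames = list(genes, samples)) + gene_baseline
  tails <- vector("list", ng)
  names(tails) <- genes
  for (g in seq_len(ng)) {
    if (direction[g] == 0) {
      tails[[g]] <- character(0)
      next
    }
    idx <- sample.int(ns, k_tail)
    tails[[g]] <- samples[sort(idx)]
    expr[g, idx] <- expr[g, idx] + direction[g] * delta[g]
  }

  # probe annotation and methylation
  np <- config$n_probes_per_gene
  probe_gene <- rep(genes, each = np)
  probes <- paste0(probe_gene, "_p", rep(seq_len(np), times = ng))
  region <- sample(names(config$region_probabilities), ng * np, replace = TRUE,
                   prob = config$region_probabilities)
  annotation <- data.frame(probe_id = probes, gene_id = probe_gene,
                           region = region, stringsAsFactors = FALSE)
  probe_baseline <- stats::rnorm(ng * np, 0, 1.5)
  meth <- matrix(stats::rnorm(ng * np * ns, 0, config$methyl_noise_sd),
                 nrow = ng * np, dimnames = list(probes, samples))
  meth <- meth + probe_baseline

  # planted per-gene, per-region methylation shifts for linked genes
  regs <- c("Promoter", "UTR", "Body")
  dm_planted <- matrix(0, nrow = ng, ncol = 3, dimnames = list(genes, regs))
  if (n_linked > 0) {
    for (g in which(linked)) {
      dm_g <- abs(config$methyl_shift) * shift_scale[g] * link_sign * direction[g]
      dm_planted[g, ] <- dm_g
      tidx <- match(tails[[g]], samples)
      pidx <- which(probe_gene == genes[g])
      for (p in pidx) {
        sh <- dm_g[[region[p]]]
        if (sh != 0) meth[p, tidx] <- meth[p, tidx] + sh
      }
    }
  }

  gene_sets <- build_gene_sets(genes, direction)

  truth_genes <- data.frame(
    gene = genes, direction = direction, pi = ifelse(direction != 0, pi_tail, 0),
    delta = ifelse(direction != 0, delta, 0),
    planted_skewness = planted_s, linked = linked,
    dM_Promoter = dm_planted[, "Promoter"],
    dM_UTR = dm_planted[, "UTR"], dM_Body = dm_planted[, "Body"],
    stringsAsFactors = FALSE
  )

  structure(list(
    expression = expr, methylation = meth, annotation = annotation,
    gene_sets = gene_sets,
    truth = list(genes = truth_genes, tails = tails),
    config = config
  ), class = "skew_cohort")
}

# A small gene-set collection: one set enriched for positively planted skew,
# one for negatively planted skew, and random filler sets, with module labels
# in the style of curated pathway summaries.
build_gene_sets <- function(genes, direction, set_size = 40, n_random = 18) {
  pos <- genes[direction > 0]
  neg <- genes[direction < 0]
  sets <- list()
  modules <- character(0)
  if (length(pos)) {
    sets[["POS_SKEW_SET"]] <- sample(pos, min(set_size, length(pos)))
    modules["POS_SKEW_SET"] <- "Immune System"
  }
  if (length(neg)) {
    sets[["NEG_SKEW_SET"]] <- sample(neg, min(set_size, length(neg)))
    modules["NEG_SKEW_SET"] <- "Metabolism"
  }
  labels <- c("Immune System", "Metabolism", "Translation", "Other")
  for (i in seq_len(n_random)) {
    nm <- sprintf("RANDOM_SET_%02d", i)
    sets[[nm]] <- sample(genes, min(set_size, length(genes)))
    modules[nm] <- labels[(i - 1) %% length(labels) + 1]
  }
  attr(sets, "modules") <- modules
  sets
}

#' Generate a noisy exponential convergence series
#'
#' Emits s_n = a * exp(-b * n) + L + Normal(0, noise_sd) at each requested
#' size, the model assumed for the convergence of subsampled gene splits.
#'
#' @param a amplitude; @param b decay rate (> 0 unless a = 0); @param L limit.
#' @param sizes increasing sample sizes.
#' @param noise_sd additive noise scale (0 for a noiseless series).
#' @param seed optional integer seed.
#' @return data.frame with columns size and split.
#' @export
generate_convergence_series <- function(a, b, L, sizes, noise_sd = 0, seed = NULL) {
  if (length(sizes) == 0) stop("sizes must be non-empty")
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be strictly increasing")
  if (b <= 0 && a != 0) stop("decay rate b must be positive")
  if (!is.null(seed)) set.seed(seed)
  s <- a * exp(-b * sizes) + L
  if (noise_sd > 0) s <- s + stats::rnorm(length(sizes), 0, noise_sd)
  data.frame(size = sizes, split = s)
}
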