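# Partition each gene's expression distribution into tail and non-tail
# patients on the side indicated by the gene's skew direction, either by a
# fixed quantile cut-off (constant tail size across genes) or by deviation
# from a robustly fitted central Gaussian mode.

new_tail_assignment <- function(direction, tail, non_tail, method, param,
                                degenerate = FALSE) {
  structure(list(direction = direction, tail = tail, non_tail = non_tail,
                 method = method, param = param, degenerate = degenerate),
            class = "tail_assignment")
}

#' Quantile tail split for one gene
#'
#' The tail is the ceiling(q * n) most extreme samples on the skew side, so
#' the tail size is constant across genes at fixed q. Ties at the cut are
#' broken by input (sample-id) order, deterministically; an all-equal vector
#' is flagged degenerate.
#'
#' @param values named numeric vector of one gene's expression per sample.
#' @param direction +1 (right tail) or -1 (left tail).
#' @param q tail proportion in (0, 0.5); default 0.1.
#' @return "tail_assignment" list: direction, tail ids, non_tail ids, method,
#'   param, degenerate flag.
#' @export
quantile_tail_split <- function(values, direction, q = 0.1) {
  if (q <= 0 || q >= 0.5) stop("q must lie in (0, 0.5)")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by sample id")
  k <- ceiling(q * length(values))
  ord <- order(if (direction > 0) -values else values, seq_along(values))
  tail_ids <- ids[sort(ord[seq_len(k)])]
  new_tail_assignment(direction, tail_ids, setdiff(ids, tail_ids),
                      "quantile", q,
                      degenerate = length(unique(values)) == 1)
}

#' Gaussian tail split for one gene
#'
#' The central mode is located by a robust Gaussian fit (median centre, MAD
#' scale with the 1.4826 normal-consistency constant); samples whose
#' standardized deviation exceeds `z_threshold` on the skew side form the
#' tail. A zero-scale (constant) vector yields an empty tail with a warning.
#'
#' @param values named numeric vector, >= 20 samples.
#' @param direction +1 or -1.
#' @param z_threshold standardized-deviation cut-off (default 2.5).
#' @return "tail_assignment" list as in [quantile_tail_split()].
#' @export
gaussian_tail_split <- function(values, direction, z_threshold = 2.5) {
  if (length(values) < 20) stop("gaussian splitting needs at least 20 samples")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by sample id")
  centre <- stats::median(values)
  scale <- stats::mad(values, constant = 1.4826)
  if (scale == 0) {
    warning("zero scale; returning an empty tail")
    return(new_tail_assignment(direction, character(0), ids,
                               "gaussian", z_threshold, degenerate = TRUE))
  }
  z <- (values - centre) / scale
  in_tail <- direction * z > z_threshold
  new_tail_assignment(direction, ids[in_tail], ids[!in_tail],
                      "gaussian", z_threshold)
}

#' Tail assignments for every skewed gene in a cohort
#'
#' Applies the chosen splitting method gene by gene, using sign(S_g) from the
#' skewness table as the tail direction. Genes with undefined or exactly zero
#' skewness are excluded (their count is reported as an attribute).
#'
#' @param x gene x sample expression matrix.
#' @param skew data.frame from [compute_skewness()] for the same matrix.
#' @param method "quantile" or "gaussian".
#' @param q,z_threshold method parameters.
#' @return named list of "tail_assignment" objects (one per skewed gene) with
#'   attributes `n_excluded` (zero/undefined skew) and `method`.
#' @export
tail_split_cohort <- function(x, skew, method = c("quantile", "gaussian"),
                              q = 0.1, z_threshold = 2.5) {
  method <- match.arg(method)
  x <- validate_matrix(x, "expression")
  skew <- skew[match(rownames(x), skew$gene), ]
  use <- !is.na(skew$skewness) & skew$skewness != 0
  out <- lapply(which(use), function(g) {
    v <- x[g, ]
    d <- if (skew$skewness[g] > 0) 1 else -1
    if (method == "quantile") quantile_tail_split(v, d, q)
    else gaussian_tail_split(v, d, z_threshold)
  })
  names(out) <- rownames(x)[use]
  attr(out, "n_excluded") <- sum(!use)
  attr(out, "method") <- method
  out
}

#' Compare tail assignments from two splitting methods
#'
#' Per-gene Jaccard index of the two tail sets over the shared genes, and,
#' when downstream significant-gene lists are supplied, the overlap
#' |A intersect B| / |A union B| of the significant genes — the summary under
#' which the two tail definitions can be judged interchangeable.
#'
#' @param a,b named lists of "tail_assignment" objects over the same genes
#'   and samples.
#' @param significant_a,significant_b optional character vectors of
#'   significant genes obtained downstream of each assignment.
#' @return list with `per_gene` data.frame (gene, jaccard), `mean_jaccard`,
#'   and `significant_overlap` (NA when no lists are supplied).
#' @export
compare_tail_methods <- function(a, b, significant_a = NULL, significant_b = NULL) {
  if (!setequal(names(a), names(b))) stop("the two assignments cover different genes")
  genes <- names(a)
  jac <- vapply(genes, function(g) {
    ta <- a[[g]]$tail
    tb <- b[[g]]$tail
    u <- union(ta, tb)
    if (length(u) == 0) return(NA_real_)
    length(intersect(ta, tb)) / length(u)
  }, numeric(1))
  sig <- NA_real_
  if (!is.null(significant_a) && !is.null(significant_b)) {
    u <- union(significant_a, significant_b)
    sig <- if (length(u) == 0) NA_real_ else
      length(intersect(significant_a, significant_b)) / length(u)
  }
  list(per_gene = data.frame(gene = genes, jaccard = unname(jac),
                             stringsAsFactors = FALSE),
       mean_jaccard = mean(jac, na.rm = TRUE),
       significant_overlap = sig)
}
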