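# Hypergeometric over-representation of gene sets within each skew-difference
# category, Benjamini-Hochberg corrected within (category x module) strata,
# with a top-10 per-module summary.

#' Over-representation test of gene sets within skew categories
#'
#' For each (category, set) pair, tests whether the set is over-represented
#' in the category relative to the universe with the upper-tail
#' hypergeometric probability P(X >= k), X ~ Hypergeometric(N, K_set, m):
#' k = overlap, K_set = set size in universe, m = category size. BH
#' adjustment is applied within each (category, module) stratum; sets with no
#' members in the universe are skipped.
#'
#' @param categories data.frame with columns gene and category (from
#'   [assign_categories()]).
#' @param sets named list of gene-id vectors, optionally with a `modules`
#'   attribute (named character vector of per-set labels).
#' @param universe gene universe; defaults to the categorized genes — the
#'   natural sampling frame for the mixture categories.
#' @param alpha adjusted-p significance level (default 0.05).
#' @return data.frame with columns set, module, category, overlap, set_size,
#'   category_size, universe_size, p, p_adj, significant; attribute
#'   `skipped_sets` lists sets with no universe members.
#' @export
overrepresentation_test <- function(categories, sets, universe = NULL,
                                    alpha = 0.05) {
  if (is.null(universe)) universe <- unique(categories$gene)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  if (!all(categories$gene %in% universe)) {
    stop("universe must contain every categorized gene")
  }
  modules <- attr(sets, "modules")
  if (is.null(modules)) {
    modules <- stats::setNames(rep("unlabelled", length(sets)), names(sets))
  }
  sets_u <- lapply(sets, intersect, y = universe)
  skipped <- names(sets_u)[lengths(sets_u) == 0]
  sets_u <- sets_u[lengths(sets_u) > 0]
  if (length(skipped)) {
    message(length(skipped), " set(s) with no members in the universe skipped")
  }
  n_u <- length(universe)
  cats <- sort(unique(categories$category))
  rows <- list()
  for (cc in cats) {
    cat_genes <- unique(categories$gene[categories$category == cc])
    m <- length(cat_genes)
    for (nm in names(sets_u)) {
      k_set <- length(sets_u[[nm]])
      k <- length(intersect(sets_u[[nm]], cat_genes))
      p <- stats::phyper(k - 1, k_set, n_u - k_set, m, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        set = nm, module = unname(modules[nm]), category = cc,
        overlap = k, set_size = k_set, category_size = m,
        universe_size = n_u, p = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (st in split(seq_len(nrow(out)),
                   list(out$category, out$module), drop = TRUE)) {
    out$p_adj[st] <- stats::p.adjust(out$p[st], method = "BH")
  }
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "skipped_sets") <- skipped
  out
}

#' Count module labels among each category's top pathways
#'
#' Within each category, ranks sets by adjusted p (ties broken by raw p, then
#' set name) and counts how many of the top `top_n` carry each module label —
#' the per-module score summarizing which biology dominates each skew
#' category. With fewer than `top_n` sets, all available are counted and the
#' shortfall noted.
#'
#' @param results data.frame from [overrepresentation_test()].
#' @param top_n pathways per category to consider (default 10).
#' @return data.frame with columns category, module, score, n_considered.
#' @export
summarize_top_pathways <- function(results, top_n = 10) {
  req <- c("set", "module", "category", "p", "p_adj")
  if (!all(req %in% names(results))) stop("results lack module labels")
  rows <- list()
  for (cc in sort(unique(results$category))) {
    sub <- results[results$category == cc, ]
    sub <- sub[order(sub$p_adj, sub$p, sub$set), ]
    n_take <- min(top_n, nrow(sub))
    if (n_take < top_n) {
      message("category ", cc, ": only ", n_take, " sets available")
    }
    top <- sub[seq_len(n_take), ]
    for (md in sort(unique(results$module))) {
      rows[[length(rows) + 1]] <- data.frame(
        category = cc, module = md, score = sum(top$module == md),
        n_considered = n_take, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
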