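# File formats: TSV matrices (first column = feature id, header = sample ids),
# GMT gene sets, JSON reports. Tab-delimited, UTF-8, '.' decimal throughout.

#' Validate a feature x sample matrix
#'
#' @param x numeric matrix with rownames (feature ids) and colnames (sample
#'   ids).
#' @param kind label used in error messages.
#' @return the matrix, invisibly unchanged.
#' @keywords internal
validate_matrix <- function(x, kind = "feature") {
  if (!is.matrix(x) || !is.numeric(x)) stop(kind, " matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(kind, " matrix needs rownames (features) and colnames (samples)")
  }
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(x))) stop(kind, " matrix contains non-finite values")
  x
}

#' Read a feature x sample TSV matrix
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @param path file path.
#' @param kind "expression" or "methylation" (error-message label only).
#' @return validated numeric matrix.
#' @export
read_matrix <- function(path, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed or empty matrix file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE)
  )
  if (nrow(df) == 0 || ncol(df) < 2) stop("malformed matrix file: ", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) stop("non-numeric column(s) in ", path, ": ",
                     paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_matrix(m, kind)
}

#' Write a feature x sample matrix as TSV
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header name of the first (feature id) column.
#' @export
write_matrix <- function(x, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a line are dropped with a warning; empty lines are skipped. The description
#' field doubles as an optional module label (e.g. "Immune System").
#'
#' @param path file path.
#' @return named list of character vectors; attribute `modules` is a named
#'   character vector of per-set labels.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  modules <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with fewer than 3 fields: ", ln)
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set ", parts[1], "; deduplicated")
      members <- unique(members)
    }
    sets[[parts[1]]] <- members
    modules[parts[1]] <- parts[2]
  }
  attr(sets, "modules") <- modules
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors; optional `modules` attribute
#'   (named character vector) used as the description field.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  modules <- attr(sets, "modules")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(modules) && nm %in% names(modules)) modules[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe annotation TSV
#'
#' Columns: probe_id, gene_id, region (Promoter, UTR or Body). Every probe
#' must map to exactly one gene and region.
#'
#' @param path file path.
#' @return data.frame with columns probe_id, gene_id, region.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_id", "region")
  if (!all(req %in% names(df))) {
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  }
  validate_annotation(df[req])
}

#' @keywords internal
validate_annotation <- function(ann) {
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe id(s) in annotation")
  bad <- setdiff(unique(ann$region), c("Promoter", "UTR", "Body"))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  ann
}
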