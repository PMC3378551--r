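#' Read a tab-separated expression table
#'
#' Expected layout: a header row of sample identifiers and one row per
#' feature, first column the feature identifier, remaining columns numeric
#' log-expression values.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2) stop("expression table needs id column plus samples: ", path)
  ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-numeric or missing value '%s' at feature '%s', sample '%s' in %s",
      vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(vals)[bad[1, 2]], path))
  }
  dimnames(num) <- list(ids, colnames(vals))
  expression_matrix(num)
}

#' Write an expression matrix as a tab-separated table
#'
#' @param x expression matrix (features x samples with dimnames).
#' @param path output path.
#' @param id_column header for the feature-id column.
#' @export
write_expression_table <- function(x, path, id_column = "feature") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-to-group table
#'
#' @param path TSV with columns sample_id, group (no header by default).
#' @param header logical; does the file carry a header row?
#' @param levels optional explicit ordering of the two group labels
#'   (second = group 2, the "up" direction).
#' @return a [group_design()].
#' @export
read_group_table <- function(path, header = FALSE, levels = NULL) {
  if (!file.exists(path)) stop("group file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2) stop("group table needs two columns: sample, group")
  assignment <- stats::setNames(tab[[2]], tab[[1]])
  group_design(assignment, levels = levels)
}

#' Read target sets from a GMT file
#'
#' GMT dialect: one set per line, fields separated by tabs —
#' set name, description, then one field per member gene. Sets whose
#' de-duplicated membership is smaller than `min_set_size` are dropped; the
#' number dropped is reported as an attribute and via `message()`.
#'
#' @param path GMT file.
#' @param min_set_size minimum (de-duplicated) member count to retain a set;
#'   default 2, the smallest set a gene-set test can use.
#' @return a [target_sets()] object with attribute `"n_dropped"`.
#' @export
read_gmt <- function(path, min_set_size = 2) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2)
  if (length(short) > 0)
    stop("malformed GMT line ", short[1], " in ", path,
         " (need at least set name and description)")
  nm <- vapply(fields, `[[`, character(1), 1)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  keep <- lengths(members) >= min_set_size
  out <- target_sets(stats::setNames(members[keep], nm[keep]))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " set(s) below min_set_size=", min_set_size, " dropped")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write target sets to a GMT file
#'
#' @param sets a [target_sets()] object.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, mem)
    paste(c(nm, desc, mem), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense 0/1 allocation matrix as target sets
#'
#' Alternative target-set input: a TSV with miRNAs in rows, mRNAs in columns
#' and entries 1 (targets) / 0 (does not target).
#'
#' @param path TSV path (header = mRNA ids, first column = miRNA ids).
#' @param min_set_size minimum targets per miRNA to retain the set.
#' @return a [target_sets()] object.
#' @export
read_allocation_matrix <- function(path, min_set_size = 2) {
  m <- read_expression_table(path) # same tabular dialect, 0/1 payload
  if (!all(m %in% c(0, 1))) stop("allocation matrix entries must be 0 or 1")
  sets <- apply(m, 1, function(r) colnames(m)[r == 1], simplify = FALSE)
  keep <- lengths(sets) >= min_set_size
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " set(s) below min_set_size=", min_set_size, " dropped")
  out <- target_sets(sets[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Intersect target sets with the measured mRNA universe
#'
#' Predicted target sets usually contain genes that were not measured on the
#' array; each set is cut down to the measured universe and the minimum-size
#' filter re-applied.
#'
#' @param sets a [target_sets()] object.
#' @param mrna measured mRNA expression matrix (or a character vector of
#'   measured mRNA ids).
#' @param min_set_size minimum retained set size after intersection.
#' @return filtered [target_sets()] with attribute `"n_dropped"`.
#' @export
intersect_universe <- function(sets, mrna, min_set_size = 2) {
  universe <- if (is.character(mrna)) mrna else rownames(mrna)
  cut <- lapply(sets, function(s) s[s %in% universe])
  keep <- lengths(cut) >= min_set_size
  if (!any(keep)) stop("no testable sets after intersecting with the ",
                       "measured mRNA universe")
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " set(s) dropped after universe intersection")
  out <- target_sets(cut[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Log2-transform and quantile-normalize an expression matrix
#'
#' Quantile normalization forces every sample (column) to share the same
#' empirical distribution: the across-sample mean of the order statistics.
#' Within-column ranks are preserved; ties receive the mean of the candidate
#' normalized values.
#'
#' @param x expression matrix; raw intensities if `log2_transform = TRUE`
#'   (must then be strictly positive), otherwise already on log scale.
#' @param log2_transform take log2 first? Default TRUE.
#' @return normalized [expression_matrix()].
#' @export
log2_quantile_normalize <- function(x, log2_transform = TRUE) {
  if (log2_transform) {
    if (any(x <= 0))
      stop("non-positive intensity encountered; cannot log2-transform")
    x <- log2(x)
  }
  out <- limma::normalizeQuantiles(unclass(x), ties = TRUE)
  expression_matrix(out, rownames(x), colnames(x))
}
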