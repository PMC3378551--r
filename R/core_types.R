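#' Construct a validated log-expression matrix
#'
#' Expression data are held as a plain numeric matrix (features in rows,
#' samples in columns, log2 scale) whose dimnames carry the feature and
#' sample identifiers. This constructor enforces the invariants every
#' downstream stage relies on: unique, non-empty identifiers on both
#' dimensions and all-finite values.
#'
#' @param values numeric matrix, features x samples.
#' @param feature_ids character vector of row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of column identifiers; defaults to
#'   `colnames(values)`.
#' @return the matrix with validated dimnames, classed `"expr_matrix"`.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match number of columns")
  if (anyNA(feature_ids) || any(!nzchar(feature_ids)))
    stop("missing or empty feature identifier")
  if (anyNA(sample_ids) || any(!nzchar(sample_ids)))
    stop("missing or empty sample identifier")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite expression value at row ",
         which(!is.finite(values), arr.ind = TRUE)[1, 1])
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Two-group design for a set of samples
#'
#' @param assignment named vector (names = sample ids) with exactly two
#'   levels; values are coerced to group labels 1 and 2 in the order of
#'   `levels` (or sorted unique order). Group 2 is the non-reference group:
#'   "up-regulated" throughout the package means higher mean in group 2.
#' @param levels optional length-2 vector fixing which label is group 1 and
#'   which is group 2.
#' @return object of class `"group_design"`: list with `group` (named integer
#'   vector in \{1,2\}), `n1`, `n2`, `labels` (original labels for 1 and 2).
#' @export
group_design <- function(assignment, levels = NULL) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be named by sample id")
  if (anyDuplicated(names(assignment)))
    stop("duplicate sample id in group assignment")
  if (anyNA(assignment)) stop("missing group label")
  lab <- as.character(assignment)
  if (is.null(levels)) levels <- sort(unique(lab))
  if (length(levels) != 2 || !setequal(unique(lab), levels))
    stop("group assignment must have exactly two levels")
  grp <- ifelse(lab == levels[2], 2L, 1L)
  names(grp) <- names(assignment)
  n1 <- sum(grp == 1L); n2 <- sum(grp == 2L)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples (n1=", n1, ", n2=", n2, ")")
  structure(list(group = grp, n1 = n1, n2 = n2, labels = levels),
            class = "group_design")
}

#' Target sets: miRNA -> set of target mRNA identifiers
#'
#' @param sets named list; names are miRNA ids, elements character vectors of
#'   mRNA ids. Duplicates within a set are removed.
#' @return object of class `"target_sets"` (the de-duplicated named list).
#' @export
target_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list of character vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate set (miRNA) name")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(sets, class = "target_sets")
}

#' @export
print.group_design <- function(x, ...) {
  cat("Two-group design:", x$n1, "vs", x$n2, "samples",
      sprintf("(group 1 = '%s', group 2 = '%s')\n", x$labels[1], x$labels[2]))
  invisible(x)
}

#' @export
print.target_sets <- function(x, ...) {
  sz <- lengths(x)
  cat(length(x), "target sets; set sizes ", min(sz), "-", max(sz),
      " (median ", stats::median(sz), ")\n", sep = "")
  invisible(x)
}

# align a design with the columns of an expression matrix
match_design <- function(x, design) {
  ids <- colnames(x)
  if (!all(ids %in% names(design$group)))
    stop("samples without group assignment: ",
         paste(setdiff(ids, names(design$group)), collapse = ", "))
  design$group[ids]
}
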