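#' Construct an expression matrix with sample group labels
#'
#' The container used throughout the package: a numeric feature-by-sample
#' matrix of intensities together with a case/control label per sample and a
#' flag recording whether values are on the linear or the log2 scale.
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (unique colnames).
#' @param groups Named character vector mapping every sample id to `"case"`
#'   or `"control"`.  Each group must contain at least two samples (the
#'   two-sample t-test downstream needs a within-group variance).
#' @param scale `"linear"` (non-negative intensities) or `"log2"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `groups` and `scale`.
#' @examples
#' v <- matrix(runif(12, 1, 100), 2, 6,
#'             dimnames = list(c("f1", "f2"), paste0("s", 1:6)))
#' g <- setNames(rep(c("case", "control"), each = 3), paste0("s", 1:6))
#' em <- expression_matrix(v, g)
#' @export
expression_matrix <- function(values, groups, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  em <- structure(list(values = values, groups = groups, scale = scale),
                  class = "ExpressionMatrix")
  validate_expression_matrix(em)
  em
}

validate_expression_matrix <- function(em) {
  v <- em$values
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    stop_ln("feature ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    stop_ln("sample ids must be present and unique")
  if (anyNA(v))
    stop_ln("expression values must not contain missing values")
  if (em$scale == "linear" && any(v < 0))
    stop_ln("negative intensities are not allowed on the linear scale")
  g <- em$groups
  missing <- setdiff(colnames(v), names(g))
  if (length(missing))
    stop_ln("samples without a group label: ", paste(missing, collapse = ", "))
  g <- g[colnames(v)]
  if (!all(g %in% c("case", "control")))
    stop_ln("group labels must be 'case' or 'control'")
  if (any(table(factor(g, c("case", "control"))) < 2))
    stop_ln("each group needs at least 2 samples")
  em$groups <- g
  invisible(em)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tb <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# log2 view of the matrix; zeros on the linear scale are floored at half the
# smallest positive value so the transform stays finite.
em_log2 <- function(em) {
  if (em$scale == "log2") return(em$values)
  v <- em$values
  if (any(v == 0)) {
    pos <- v[v > 0]
    eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
    v <- pmax(v, eps)
  }
  log2(v)
}

sample_ids <- function(em) colnames(em$values)
case_ids <- function(em) names(em$groups)[em$groups == "case"]
control_ids <- function(em) names(em$groups)[em$groups == "control"]

#' Read a feature-by-sample expression matrix from TSV
#'
#' The matrix file has the feature id in the first column and one column per
#' sample (header row carries the sample ids).  The groups file is a
#' two-column, header-less TSV mapping every sample id to `case` or
#' `control`.  Rows containing any missing value are dropped, with the count
#' reported via [message()].
#'
#' @param path Path to the matrix TSV.
#' @param groups_path Path to the two-column sample-group TSV.
#' @param scale Scale of the stored values (`"linear"` or `"log2"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, groups_path,
                                   scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_ln(path, ": expected a feature column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop_ln(path, ": duplicate feature ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  dropped <- rowSums(is.na(m)) > 0
  if (any(dropped)) {
    ln_note(sum(dropped), " feature row(s) with missing values dropped from ",
            basename(path))
    m <- m[!dropped, , drop = FALSE]
  }
  if (scale == "linear" && any(m < 0))
    stop_ln(path, ": negative value found but scale = 'linear'")
  gt <- read.delim(groups_path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(gt) < 2) stop_ln(groups_path, ": expected two columns")
  groups <- setNames(as.character(gt[[2]]), as.character(gt[[1]]))
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing))
    stop_ln(groups_path, ": no group for sample(s): ",
            paste(missing, collapse = ", "))
  em <- expression_matrix(m, groups[colnames(m)], scale)
  attr(em, "n_dropped") <- sum(dropped)
  em
}

#' Write an expression matrix (and optionally its group map) to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output TSV path for the matrix.
#' @param groups_path Optional path for the two-column group map.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, groups_path = NULL) {
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path))
    write.table(data.frame(names(em$groups), unname(em$groups)),
                groups_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}
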