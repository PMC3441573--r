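#' Expression matrix with replicate structure
#'
#' Container for a log-scale expression matrix (features in rows, samples in
#' columns) together with the map from sample to cell type.  Both transcription
#' factor (TF) panels and target gene panels are stored this way; the model
#' machinery draws predictor values \eqn{x_{ij}} from a TF matrix and responses
#' \eqn{y_i} from a gene matrix.
#'
#' @param values numeric matrix, features x samples, with row and column names.
#'   Values are assumed to be on a log scale already.
#' @param replicate_map named character vector mapping each sample id (name) to
#'   its cell-type label (value).  Every column of `values` must be present.
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` and `replicate_map`.
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("TF1", "TF2"), paste0("s", 1:4)))
#' rm <- setNames(c("ct1", "ct1", "ct2", "ct2"), colnames(m))
#' em <- expression_matrix(m, rm)
#' cell_types(em)
#' @export
expression_matrix <- function(values, replicate_map) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("expression values contain missing entries")
  if (!is.character(replicate_map) || is.null(names(replicate_map)))
    stop("'replicate_map' must be a named character vector")
  missing <- setdiff(colnames(values), names(replicate_map))
  if (length(missing))
    stop("samples absent from replicate map: ", paste(missing, collapse = ", "))
  structure(
    list(values = values,
         replicate_map = replicate_map[colnames(values)]),
    class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " features x ",
      ncol(x$values), " samples (",
      length(unique(x$replicate_map)), " cell types)\n", sep = "")
  invisible(x)
}

#' Feature and sample accessors
#'
#' @param x an [expression_matrix()].
#' @return Character vectors of feature ids, sample ids, or cell-type labels.
#' @export
features <- function(x) rownames(x$values)

#' @rdname features
#' @export
samples <- function(x) colnames(x$values)

#' @rdname features
#' @export
cell_types <- function(x) unique(unname(x$replicate_map))

#' Samples belonging to given cell types
#'
#' @param x an [expression_matrix()].
#' @param types character vector of cell-type labels.
#' @return Character vector of sample ids whose cell type is in `types`.
#' @export
samples_of <- function(x, types) {
  names(x$replicate_map)[x$replicate_map %in% types]
}

#' Subset an ExpressionMatrix
#'
#' @param x an [expression_matrix()].
#' @param features,samples optional character vectors selecting rows / columns.
#' @return A new [expression_matrix()].
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) {
    bad <- setdiff(features, rownames(v))
    if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(v))
    if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, x$replicate_map)
}

#' Collapse replicates to cell-type means
#'
#' Averages the samples of each cell type into one column.  Model-comparison
#' tests use the collapsed panel: biological replicates share their
#' cell-type-level variation, so treating them as independent observations
#' would overstate the residual degrees of freedom (pseudo-replication).
#'
#' @param x an [expression_matrix()].
#' @return An [expression_matrix()] with one column per cell type.
#' @export
collapse_replicates <- function(x) {
  cts <- cell_types(x)
  v <- vapply(cts, function(ct)
    rowMeans(x$values[, samples_of(x, ct), drop = FALSE]),
    numeric(nrow(x$values)))
  v <- matrix(v, nrow(x$values), length(cts),
              dimnames = list(rownames(x$values), cts))
  expression_matrix(v, stats::setNames(cts, cts))
}
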