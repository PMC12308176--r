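#' Cell-by-feature matrix for one modality
#'
#' The pipeline's universal currency: a cells x features value matrix (dense
#' base matrix or sparse `Matrix`), ordered unique cell and feature
#' identifiers, and a modality tag.
#'
#' @param values numeric matrix or sparse `Matrix`, cells in rows.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @param feature_ids character vector of unique feature identifiers, one per
#'   column.
#' @param modality `"RNA"` or `"ATAC"`.
#' @return An object of class `cell_matrix`: a list with elements `values`,
#'   `cell_ids`, `feature_ids`, `modality`.
#' @examples
#' m <- cell_matrix(matrix(0:3, 2), c("c1", "c2"), c("g1", "g2"), "RNA")
#' dim(m)
#' @export
cell_matrix <- function(values, cell_ids = rownames(values),
                        feature_ids = colnames(values),
                        modality = c("RNA", "ATAC")) {
  modality <- match.arg(modality)
  if (!(is.matrix(values) || is(values, "Matrix")))
    stop("`values` must be a matrix or Matrix", call. = FALSE)
  if (is.null(cell_ids))
    cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(feature_ids))
    feature_ids <- paste0("feature_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) != nrow(values)", call. = FALSE)
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) != ncol(values)", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop(sprintf("duplicate cell id '%s'",
                 cell_ids[anyDuplicated(cell_ids)]), call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop(sprintf("duplicate feature id '%s'",
                 feature_ids[anyDuplicated(feature_ids)]), call. = FALSE)
  vals <- if (is.matrix(values)) values[which(!is.finite(values))] else
    values@x[!is.finite(values@x)]
  if (length(vals))
    stop("`values` contains non-finite entries", call. = FALSE)
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 feature_ids = feature_ids, modality = modality),
            class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' @export
print.cell_matrix <- function(x, ...) {
  nz <- if (is(x$values, "sparseMatrix")) length(x$values@x)
        else sum(x$values != 0)
  cat(sprintf("<cell_matrix> %s: %d cells x %d features (%.1f%% non-zero)\n",
              x$modality, nrow(x$values), ncol(x$values),
              100 * nz / max(1, prod(dim(x$values)))))
  invisible(x)
}

#' @rdname cell_matrix
#' @param x object to coerce (matrix, `Matrix` or `cell_matrix`).
#' @export
as_cell_matrix <- function(x, modality = c("RNA", "ATAC")) {
  if (inherits(x, "cell_matrix")) return(x)
  cell_matrix(x, modality = match.arg(modality))
}

# Dense numeric values of a cell_matrix (internal).
dense_values <- function(m) {
  v <- if (inherits(m, "cell_matrix")) m$values else m
  if (is(v, "Matrix")) as.matrix(v) else v
}
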