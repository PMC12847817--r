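#' Sparse cell-by-feature count matrix with a negative-probe mask
#'
#' The central RNA container of the package: a sparse non-negative integer
#' matrix of cells (rows) by panel features (columns), together with a logical
#' mask marking which features are negative probes (panel probes with no
#' cellular target, used to estimate background noise).
#'
#' @param counts matrix or \code{Matrix::sparseMatrix} of non-negative integer
#'   counts, cells in rows, features in columns; dimnames required.
#' @param negprobe_mask optional logical vector, one entry per feature; if
#'   \code{NULL} it is inferred from \code{negprobe_prefix}.
#' @param negprobe_prefix feature-name prefix identifying negative probes
#'   (vendor convention; default \code{"NegPrb"}).
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (dgCMatrix), \code{negprobe_mask} (named logical).
#' @export
count_matrix <- function(counts, negprobe_mask = NULL, negprobe_prefix = "NegPrb") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix requires cell (row) and feature (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature ids in count matrix")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stop("counts must be non-negative integers")
  if (is.null(negprobe_mask)) {
    negprobe_mask <- startsWith(colnames(counts), negprobe_prefix)
  }
  if (length(negprobe_mask) != ncol(counts))
    stop("negprobe_mask length must equal the number of features")
  negprobe_mask <- stats::setNames(as.logical(negprobe_mask), colnames(counts))
  structure(list(counts = counts, negprobe_mask = negprobe_mask),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d features (%d negative probes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$negprobe_mask)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Cell ids of a count or intensity matrix
#' @param x a \code{count_matrix} or \code{intensity_matrix}
#' @return character vector of cell ids
#' @export
cell_ids <- function(x) rownames(x$counts)

#' Feature ids of a count or intensity matrix
#' @param x a \code{count_matrix} or \code{intensity_matrix}
#' @return character vector of feature ids
#' @export
feature_ids <- function(x) colnames(x$counts)

#' Gene (non-negative-probe) submatrix as a sparse matrix
#' @param x a \code{count_matrix}
#' @return dgCMatrix of gene features only
#' @export
gene_counts <- function(x) x$counts[, !x$negprobe_mask, drop = FALSE]

#' Negative-probe submatrix as a sparse matrix
#' @param x a \code{count_matrix}
#' @return dgCMatrix of negative-probe features only
#' @export
negprobe_counts <- function(x) x$counts[, x$negprobe_mask, drop = FALSE]

#' Dense cell-by-channel protein intensity matrix with negative-probe channels
#'
#' Protein analogue of \code{\link{count_matrix}}: real-valued (fluorescence
#' intensity) rather than integer, with negative-probe channels marked.
#'
#' @param values numeric matrix, cells in rows, channels in columns; dimnames
#'   required; values must be non-negative and finite.
#' @param negprobe_mask optional logical per channel; inferred from
#'   \code{negprobe_prefix} when \code{NULL}.
#' @param negprobe_prefix channel-name prefix identifying negative probes.
#' @return object of class \code{intensity_matrix}
#' @export
intensity_matrix <- function(values, negprobe_mask = NULL, negprobe_prefix = "NegPrb") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity_matrix requires cell (row) and channel (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(values))) stop("duplicate channel ids")
  if (any(!is.finite(values)) || any(values < 0))
    stop("intensities must be finite and non-negative")
  if (is.null(negprobe_mask)) negprobe_mask <- startsWith(colnames(values), negprobe_prefix)
  if (length(negprobe_mask) != ncol(values))
    stop("negprobe_mask length must equal the number of channels")
  negprobe_mask <- stats::setNames(as.logical(negprobe_mask), colnames(values))
  structure(list(counts = values, negprobe_mask = negprobe_mask),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d cells x %d channels (%d negative probes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$negprobe_mask)))
  invisible(x)
}

# required columns of a cell metadata table
.cell_table_required <- c("cell_id", "x_um", "y_um", "fov", "patient", "group", "area")

.group_levels <- c("IBD", "PD", "NHC")

#' Validate a per-cell metadata table
#'
#' Checks the contract of the cell table: one row per cell, coordinates in
#' micrometres within a field of view (FOV), participant id, disease group in
#' \{IBD, PD, NHC\} and a positive segmented cell area. Extra columns (e.g.
#' morphology-marker means) are preserved.
#'
#' @param df data.frame with at least the required columns
#'   \code{cell_id, x_um, y_um, fov, patient, group, area}.
#' @return the validated data.frame (invisibly the same object)
#' @export
validate_cell_table <- function(df) {
  miss <- setdiff(.cell_table_required, names(df))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id values")
  if (!all(df$group %in% .group_levels))
    stop("group values outside {IBD, PD, NHC}: ",
         paste(unique(setdiff(df$group, .group_levels)), collapse = ", "))
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop("non-finite coordinates")
  if (any(!is.finite(df$area)) || any(df$area <= 0)) stop("area must be > 0")
  df$cell_id <- as.character(df$cell_id)
  df
}

# internal: check that a count/intensity container and a cell table describe
# the same cells in the same order
.check_aligned <- function(mat, cells) {
  if (!identical(rownames(mat$counts), cells$cell_id))
    stop("cell ids of the matrix and the cell table are misaligned")
  invisible(TRUE)
}
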