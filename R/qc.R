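#' Iterative two-sided Grubbs outlier test
#'
#' Flags outliers in a univariate sample by repeatedly testing the most
#' extreme value: G = max|x - mean| / sd is compared with the critical value
#' G_crit(n, alpha) = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)), where t is
#' the upper alpha/(2n) quantile of Student's t with n-2 degrees of freedom
#' (alpha/n for the one-sided variant). When \code{iterative}, the rejected
#' value is removed and the test repeated on the remainder until no rejection.
#'
#' @param values numeric vector
#' @param alpha significance level (default 0.01, the study value for cell areas)
#' @param two_sided two-sided test (default)
#' @param iterative repeat after removing each detected outlier
#' @return logical vector of outlier flags in input order; fewer than 3 values
#'   (the minimum for the test) or zero variance give all-FALSE
#' @export
grubbs_outliers <- function(values, alpha = 0.01, two_sided = TRUE, iterative = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  flags <- logical(length(values))
  active <- which(is.finite(values))
  repeat {
    n <- length(active)
    if (n < 3) break
    x <- values[active]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    p <- if (two_sided) alpha / (2 * n) else alpha / n
    tq <- stats::qt(1 - p, df = n - 2)
    Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G > Gcrit) {
      flags[active[i]] <- TRUE
      active <- active[-i]
      if (!iterative) break
    } else break
  }
  flags
}

# assemble a QC report from a logical flag matrix
.qc_report <- function(flags, cell_id) {
  pass <- !Reduce(`|`, flags)
  df <- data.frame(cell_id = cell_id, flags, pass = pass,
                   stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(
    flags = df,
    summary = list(
      n_cells = length(cell_id),
      pass_fraction = mean(pass),
      flag_counts = vapply(flags, sum, 0L)
    )
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("qc_report: %d cells, %.2f%% pass\n", s$n_cells, 100 * s$pass_fraction))
  print(s$flag_counts)
  invisible(x)
}

#' Per-cell RNA quality control
#'
#' Applies the six RNA flag rules on raw counts: low total counts, high
#' negative-probe fraction, total counts not exceeding the number of detected
#' genes, too few detected features, cell-area Grubbs outliers (per FOV), and
#' a high mean negative-probe count. Flagged cells should be removed from
#' downstream analysis.
#'
#' @param counts \code{\link{count_matrix}} of raw counts
#' @param cells cell table aligned with \code{counts} (same cells, same order)
#' @param params \code{\link{qc_params}}
#' @return \code{qc_report} with columns low_counts, high_negprobe,
#'   counts_not_exceed_features, low_features, area_outlier, high_mean_neg, pass
#' @export
rna_cell_qc <- function(counts, cells, params = qc_params()) {
  cells <- validate_cell_table(cells)
  .check_aligned(counts, cells)
  g <- gene_counts(counts)
  np <- negprobe_counts(counts)
  gene_tot <- Matrix::rowSums(g)
  neg_tot <- if (ncol(np)) Matrix::rowSums(np) else rep(0, nrow(g))
  all_tot <- gene_tot + neg_tot
  n_feat <- Matrix::rowSums(g > 0)
  qc_total <- if (params$rna_counts_include_negprobes) all_tot else gene_tot

  low_counts <- qc_total < params$rna_min_counts
  neg_frac <- ifelse(all_tot > 0, neg_tot / all_tot, 0)
  high_negprobe <- neg_frac >= params$rna_max_negprobe_frac
  counts_not_exceed_features <- gene_tot <= n_feat
  low_features <- n_feat < params$rna_min_features
  mean_neg <- if (ncol(np)) neg_tot / ncol(np) else rep(0, nrow(g))
  high_mean_neg <- mean_neg >= params$rna_mean_neg_max
  grp <- if (params$grubbs_scope == "fov") cells$fov else rep("slide", nrow(cells))
  area_outlier <- stats::ave(cells$area, grp, FUN = function(a)
    as.numeric(grubbs_outliers(a, alpha = params$grubbs_alpha))) > 0

  .qc_report(list(low_counts = low_counts,
                  high_negprobe = high_negprobe,
                  counts_not_exceed_features = counts_not_exceed_features,
                  low_features = low_features,
                  area_outlier = area_outlier,
                  high_mean_neg = high_mean_neg),
             cells$cell_id)
}

#' Per-cell protein quality control
#'
#' Percentiles are computed per protein across all cells on the slide before
#' any removal. A cell is flagged \code{insufficient_high} when fewer than
#' half of the (non-negative-probe) proteins sit at or above their 90th
#' percentile, \code{insufficient_low} when fewer than 10 proteins sit at or
#' below their 50th percentile, \code{negprobe_window} when the mean
#' negative-probe intensity falls outside the 2-15 window, and \code{area_outlier} by
#' the per-FOV Grubbs test.
#'
#' @param intensities \code{\link{intensity_matrix}} of raw intensities
#' @param cells aligned cell table
#' @param params \code{\link{qc_params}}
#' @return \code{qc_report}
#' @export
protein_cell_qc <- function(intensities, cells, params = qc_params()) {
  cells <- validate_cell_table(cells)
  .check_aligned(intensities, cells)
  v <- intensities$counts[, !intensities$negprobe_mask, drop = FALSE]
  npv <- intensities$counts[, intensities$negprobe_mask, drop = FALSE]
  if (nrow(v) < 2) stop("protein QC needs at least 2 cells to define percentiles")
  if (params$prot_high_scope == "per_protein") {
    q_hi <- apply(v, 2, stats::quantile, probs = params$prot_high_pct / 100, names = FALSE)
    q_lo <- apply(v, 2, stats::quantile, probs = params$prot_low_pct / 100, names = FALSE)
    n_hi <- rowSums(sweep(v, 2, q_hi, `>=`))
    n_lo <- rowSums(sweep(v, 2, q_lo, `<=`))
  } else {
    # per-cell reading: percentiles of each cell's own protein vector
    q_hi <- apply(v, 1, stats::quantile, probs = params$prot_high_pct / 100, names = FALSE)
    q_lo <- apply(v, 1, stats::quantile, probs = params$prot_low_pct / 100, names = FALSE)
    n_hi <- rowSums(v >= q_hi)
    n_lo <- rowSums(v <= q_lo)
  }
  insufficient_high <- n_hi / ncol(v) < params$prot_high_frac
  insufficient_low <- n_lo < params$prot_min_low
  mean_neg <- if (ncol(npv)) rowMeans(npv) else rep((params$prot_neg_lo + params$prot_neg_hi) / 2, nrow(v))
  negprobe_window <- mean_neg < params$prot_neg_lo | mean_neg > params$prot_neg_hi
  grp <- if (params$grubbs_scope == "fov") cells$fov else rep("slide", nrow(cells))
  area_outlier <- stats::ave(cells$area, grp, FUN = function(a)
    as.numeric(grubbs_outliers(a, alpha = params$grubbs_alpha))) > 0

  .qc_report(list(insufficient_high = insufficient_high,
                  insufficient_low = insufficient_low,
                  negprobe_window = negprobe_window,
                  area_outlier = area_outlier),
             cells$cell_id)
}

#' Subset a count/intensity matrix and cell table to QC-passing cells
#'
#' @param mat \code{count_matrix} or \code{intensity_matrix}
#' @param cells aligned cell table
#' @param report \code{qc_report} from \code{\link{rna_cell_qc}} or
#'   \code{\link{protein_cell_qc}}
#' @return list(mat, cells) restricted to passing cells
#' @export
apply_qc <- function(mat, cells, report) {
  keep <- report$flags$pass
  mat$counts <- mat$counts[keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  rownames(cells) <- NULL
  list(mat = mat, cells = cells)
}

#' Library-size log normalization of RNA counts
#'
#' Each cell's gene counts are scaled to the median library size across cells
#' and log(1 + x)-transformed; negative-probe features are excluded. This is a
#' monotone variance-stabilizing normalization suited to targeted panels; the
#' downstream rank-based statistics only require monotonicity.
#'
#' @param counts \code{\link{count_matrix}} of QC-passing cells
#' @param method currently \code{"libsize_log"}
#' @return sparse real matrix (cells x genes)
#' @export
normalize_rna <- function(counts, method = "libsize_log") {
  method <- match.arg(method, "libsize_log")
  g <- gene_counts(counts)
  lib <- Matrix::rowSums(g)
  if (any(lib == 0))
    stop("zero-count cell(s) present; remove by QC before normalization")
  target <- stats::median(lib)
  scaled <- Matrix::Diagonal(x = target / lib) %*% g
  dimnames(scaled) <- dimnames(g)
  out <- scaled
  out@x <- log1p(out@x)
  out
}

#' Average-total-intensity scaling and arcsinh protein normalization
#'
#' Each cell's channel intensities are scaled by (mean total intensity across
#' cells) / (cell total intensity), then transformed by asinh(x / cofactor)
#' with the study cofactor of 50. Negative-probe channels are excluded.
#'
#' @param intensities \code{\link{intensity_matrix}} of QC-passing cells
#' @param params \code{\link{qc_params}} (uses \code{arcsinh_cofactor})
#' @return dense real matrix (cells x proteins)
#' @export
normalize_protein <- function(intensities, params = qc_params()) {
  v <- intensities$counts[, !intensities$negprobe_mask, drop = FALSE]
  tot <- rowSums(v)
  if (any(tot == 0)) stop("zero-total cell(s); remove by QC before normalization")
  scaled <- v * (mean(tot) / tot)
  asinh(scaled / params$arcsinh_cofactor)
}
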