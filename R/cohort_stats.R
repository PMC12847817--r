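#' Disease-vs-control cell-type composition testing
#'
#' For each cluster and each comparison (IBD vs NHC, PD vs NHC): a pooled 2x2
#' chi-squared test of (in-cluster vs not) by (disease vs NHC); a patient-level
#' Wilcoxon rank-sum test on per-patient cluster proportions (accounting for
#' patient variability); the pooled-proportion fold change; Benjamini-Yekutieli
#' adjustment of the chi-squared p-values across all cluster x comparison rows;
#' and a significance code driven by the adjusted p gated by the fold-change
#' bounds (FC > 1.5 or < 0.66).
#'
#' @param annotation \code{annotation_result}; only retained cells are used.
#'   The \code{refined} column is used when present, else \code{label}.
#' @param cells cell table covering the annotated cells (matched by cell_id)
#' @param params \code{\link{stat_params}}
#' @param comparisons disease groups compared against NHC
#' @return data.frame (class \code{composition_result}) with one row per
#'   cluster x comparison: cell counts, chi2, chi2_p, wilcoxon_p, fc, adj_p,
#'   code
#' @export
composition_test <- function(annotation, cells, params = stat_params(),
                             comparisons = c("IBD", "PD")) {
  lab_col <- if ("refined" %in% names(annotation)) "refined" else "label"
  ann <- annotation[annotation$retained & !is.na(annotation[[lab_col]]), , drop = FALSE]
  m <- match(ann$cell_id, cells$cell_id)
  if (anyNA(m)) stop("annotated cells missing from the cell table")
  df <- data.frame(label = ann[[lab_col]],
                   patient = cells$patient[m],
                   group = cells$group[m],
                   stringsAsFactors = FALSE)
  clusters <- sort(unique(df$label))
  rows <- list()
  for (cmp in comparisons) {
    dis <- df[df$group == cmp, ]
    ctl <- df[df$group == "NHC", ]
    if (!nrow(dis) || !nrow(ctl))
      stop("comparison ", cmp, " vs NHC: a group has no cells")
    for (cl in clusters) {
      a <- sum(dis$label == cl); b <- nrow(dis) - a
      c_ <- sum(ctl$label == cl); d <- nrow(ctl) - c_
      tab <- matrix(c(a, b, c_, d), 2, 2)
      ch <- if (a + c_ == 0) list(statistic = NA_real_, p = NA_real_)
            else chi_square_2x2(tab, correction = params$chi2_correction)
      fc <- if (c_ == 0) {
        warning("cluster ", cl, " absent in NHC: FC undefined")
        NA_real_
      } else (a / nrow(dis)) / (c_ / nrow(ctl))
      # per-patient proportions of this cluster
      pp <- function(d0) {
        tapply(d0$label == cl, d0$patient, mean)
      }
      wp <- wilcoxon_rank_sum(as.numeric(pp(dis)), as.numeric(pp(ctl)))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, comparison = paste0(cmp, "_vs_NHC"),
        n_disease = a, n_disease_other = b, n_nhc = c_, n_nhc_other = d,
        chi2 = ch$statistic, chi2_p = ch$p, wilcoxon_p = wp, fc = fc,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$adj_p <- NA_real_
  ok <- !is.na(res$chi2_p)
  res$adj_p[ok] <- benjamini_yekutieli(res$chi2_p[ok])
  res$code <- significance_code(res$adj_p, res$fc, params)
  class(res) <- c("composition_result", "data.frame")
  res
}

#' Star codes from adjusted p-values gated by fold-change bounds
#'
#' @param adj_p adjusted p-values
#' @param fc fold changes; a code is emitted only when FC > \code{fc_enrich}
#'   or FC < \code{fc_deplete}
#' @param params \code{\link{stat_params}}
#' @return character vector of codes ("", "*", "**", "***")
#' @export
significance_code <- function(adj_p, fc, params = stat_params()) {
  lv <- sort(params$star_levels, decreasing = TRUE)  # 0.05, 0.01, 0.001
  code <- rep("", length(adj_p))
  for (i in seq_along(lv)) {
    code[!is.na(adj_p) & adj_p < lv[i]] <- names(lv)[i]
  }
  gate <- !is.na(fc) & (fc > params$fc_enrich | fc < params$fc_deplete)
  code[!gate] <- ""
  code
}

#' Per-cluster differential expression between a disease group and NHC
#'
#' Cell-level Wilcoxon rank-sum test per gene on normalized expression within
#' one cluster; fold change as the ratio of arm means (with a small epsilon);
#' Benjamini-Yekutieli adjustment within the (cluster, comparison) gene
#' family; volcano categories per \code{\link{volcano_classify}}.
#'
#' @param norm_matrix cells-by-genes normalized matrix (from
#'   \code{\link{normalize_rna}}), rows named by cell_id
#' @param annotation \code{annotation_result} (retained cells only are used)
#' @param cells cell table (matched by cell_id)
#' @param cluster cluster label tested (matched against refined labels when
#'   present); use \code{NULL} to test all retained cells together
#' @param comparison disease group compared against NHC ("IBD" or "PD")
#' @param params \code{\link{stat_params}}
#' @return data.frame (class \code{de_result}): gene, mean_disease, mean_nhc,
#'   fc, log2fc, p, adj_p, category
#' @export
differential_expression <- function(norm_matrix, annotation, cells, cluster,
                                    comparison = c("IBD", "PD"),
                                    params = stat_params()) {
  comparison <- match.arg(comparison)
  lab_col <- if ("refined" %in% names(annotation)) "refined" else "label"
  ann <- annotation[annotation$retained, , drop = FALSE]
  if (!is.null(cluster)) ann <- ann[!is.na(ann[[lab_col]]) & ann[[lab_col]] == cluster, ]
  m <- match(ann$cell_id, cells$cell_id)
  grp <- cells$group[m]
  keep <- grp %in% c(comparison, "NHC")
  ids <- ann$cell_id[keep]; grp <- grp[keep]
  n1 <- sum(grp == comparison); n2 <- sum(grp == "NHC")
  if (n1 < params$de_min_cells || n2 < params$de_min_cells)
    stop("cluster ", if (is.null(cluster)) "(all)" else cluster,
         " has fewer than ", params$de_min_cells, " cells in an arm")
  M <- as.matrix(norm_matrix[ids, , drop = FALSE])
  in_dis <- grp == comparison
  p <- .rank_sum_p_matrix(M, in_dis)
  mu_d <- colMeans(M[in_dis, , drop = FALSE])
  mu_c <- colMeans(M[!in_dis, , drop = FALSE])
  fc <- (mu_d + params$de_eps) / (mu_c + params$de_eps)
  adj <- benjamini_yekutieli(p)
  res <- data.frame(gene = colnames(M), mean_disease = mu_d, mean_nhc = mu_c,
                    fc = fc, log2fc = log2(fc), p = p, adj_p = adj,
                    category = volcano_classify(fc, p, adj, params),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Volcano plot categories
#'
#' dark_red: adjusted p < 0.05 and FC > 1.2; light_red: raw p < 0.05 and
#' FC > 1.2 (not dark); dark_blue / light_blue mirror with FC < 0.83; else ns.
#'
#' @param fc,p,adj_p vectors of fold change, raw and adjusted p
#' @param params \code{\link{stat_params}}
#' @return character vector of categories
#' @export
volcano_classify <- function(fc, p, adj_p, params = stat_params()) {
  stopifnot(length(fc) == length(p), length(p) == length(adj_p))
  out <- rep("ns", length(fc))
  up <- fc > params$de_fc_up
  dn <- fc < params$de_fc_down
  out[p < params$alpha & up] <- "light_red"
  out[adj_p < params$alpha & up] <- "dark_red"
  out[p < params$alpha & dn] <- "light_blue"
  out[adj_p < params$alpha & dn] <- "dark_blue"
  out
}

#' Raw-count expression density summaries per group and refined type
#'
#' For one gene: the mean raw count and a (renormalized) kernel-density
#' estimate on a shared grid, per disease group x refined cell type, as
#' plotted in cell-type-specific density panels.
#'
#' @param counts \code{\link{count_matrix}} of raw counts
#' @param annotation \code{annotation_result} with refined labels
#' @param cells cell table
#' @param gene gene symbol (must be in the panel)
#' @param grid_n number of grid points
#' @return list(summary = data.frame(group, type, n, mean_count),
#'   density = long data.frame(group, type, x, density)); each curve
#'   integrates to 1 on the grid (trapezoid rule)
#' @export
expression_density <- function(counts, annotation, cells, gene, grid_n = 200L) {
  if (!gene %in% colnames(counts$counts)) stop("gene not in panel: ", gene)
  lab_col <- if ("refined" %in% names(annotation)) "refined" else "label"
  ann <- annotation[annotation$retained & !is.na(annotation[[lab_col]]), ]
  x_all <- counts$counts[ann$cell_id, gene]
  grp <- cells$group[match(ann$cell_id, cells$cell_id)]
  typ <- ann[[lab_col]]
  lo <- 0; hi <- max(x_all, 1)
  sum_rows <- list(); den_rows <- list()
  for (g in unique(grp)) for (t in unique(typ[grp == g])) {
    v <- x_all[grp == g & typ == t]
    if (!length(v)) next
    sum_rows[[length(sum_rows) + 1L]] <-
      data.frame(group = g, type = t, n = length(v), mean_count = mean(v))
    if (length(v) >= 2 && stats::sd(v) > 0) {
      d <- stats::density(v, from = lo, to = hi, n = grid_n)
      area <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
      den_rows[[length(den_rows) + 1L]] <-
        data.frame(group = g, type = t, x = d$x, density = d$y / area)
    }
  }
  list(summary = do.call(rbind, sum_rows), density = do.call(rbind, den_rows))
}
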