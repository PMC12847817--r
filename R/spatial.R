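#' Within-FOV neighbor pairs inside a radius
#'
#' All unordered cell pairs whose Euclidean distance is at most
#' \code{radius_um} (closed ball), computed strictly within each field of
#' view; no self-pairs, each pair listed once.
#'
#' @param cells cell table with x_um, y_um, fov
#' @param radius_um neighborhood radius in micrometres (study value 25)
#' @return data.frame: cell_i, cell_j (ids, i before j in table order),
#'   distance, fov
#' @export
neighbor_pairs <- function(cells, radius_um = 25) {
  stopifnot(radius_um > 0)
  cells <- validate_cell_table(cells)
  out <- list()
  for (f in unique(cells$fov)) {
    sub <- cells[cells$fov == f, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    d <- as.matrix(stats::dist(cbind(sub$x_um, sub$y_um)))
    idx <- which(d <= radius_um & upper.tri(d), arr.ind = TRUE)
    if (!nrow(idx)) next
    out[[length(out) + 1L]] <- data.frame(
      cell_i = sub$cell_id[idx[, 1]],
      cell_j = sub$cell_id[idx[, 2]],
      distance = d[idx],
      fov = f, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(cell_i = character(), cell_j = character(),
                      distance = numeric(), fov = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marker-positive/negative stratification of a source cell type
#'
#' Cells of the source type are split by raw marker detection (count at or
#' above \code{marker_min_count}) into \code{<type>_<marker>+} and
#' \code{<type>_<marker>-}; all other cells keep their refined label.
#' Positivity is defined on raw counts because detection is the relevant
#' event in imaging panels.
#'
#' @param annotation \code{annotation_result} with refined labels
#' @param counts \code{\link{count_matrix}} of raw counts
#' @param params \code{\link{spatial_params}}
#' @return named character vector of strata, one entry per annotated cell
#' @export
marker_stratify <- function(annotation, counts, params = spatial_params()) {
  if (!params$marker_gene %in% colnames(counts$counts))
    stop("marker gene not in panel: ", params$marker_gene)
  lab_col <- if ("refined" %in% names(annotation)) "refined" else "label"
  lab <- annotation[[lab_col]]
  mk <- counts$counts[annotation$cell_id, params$marker_gene]
  src <- !is.na(lab) & lab == params$source_type
  lab[src] <- paste0(params$source_type, "_", params$marker_gene,
                     ifelse(mk[src] >= params$marker_min_count, "+", "-"))
  stats::setNames(lab, annotation$cell_id)
}

#' Ligand-receptor interaction scores over a neighbor graph
#'
#' For each (target type, ligand, receptor): the mean, over directed
#' source-to-target neighbor pairs whose source carries
#' \code{source_stratum}, of ligand expression in the source times receptor
#' expression in the target. LR pairs whose genes are absent from the panel
#' are skipped with a message; (target, LR) combinations with no qualifying
#' edge are absent from the result.
#'
#' @param pairs neighbor pairs from \code{\link{neighbor_pairs}}
#' @param norm_expr cells-by-genes normalized expression, rows named by cell id
#' @param strata per-cell stratum labels from \code{\link{marker_stratify}}
#' @param lr_table data.frame(ligand, receptor)
#' @param source_stratum stratum acting as the signal source
#' @param params \code{\link{spatial_params}}
#' @return data.frame: target, ligand, receptor, score, n_pairs
#' @export
lr_interaction_scores <- function(pairs, norm_expr, strata, lr_table,
                                  source_stratum, params = spatial_params()) {
  ed <- .directed_edges(pairs, names(strata))
  lr <- .usable_lr(lr_table, colnames(norm_expr))
  V <- .edge_values(ed, norm_expr, lr)
  .score_edges(ed, V, unname(strata), lr, source_stratum)
}

# directed edge index list: each unordered pair in both orientations,
# as integer indices into the cell id vector
.directed_edges <- function(pairs, ids) {
  i <- match(pairs$cell_i, ids); j <- match(pairs$cell_j, ids)
  if (anyNA(i) || anyNA(j)) stop("pair endpoints missing from strata/expression")
  list(src = c(i, j), tgt = c(j, i))
}

.usable_lr <- function(lr_table, genes) {
  ok <- lr_table$ligand %in% genes & lr_table$receptor %in% genes
  if (any(!ok))
    message(sum(!ok), " ligand-receptor pair(s) skipped: gene not in panel")
  lr_table[ok, , drop = FALSE]
}

# per-edge ligand(source) x receptor(target) products, one column per LR pair;
# depends only on expression and geometry, not on labels, so it is computed
# once and reused across label permutations
.edge_values <- function(ed, norm_expr, lr) {
  if (!nrow(lr)) return(matrix(0, length(ed$src), 0))
  L <- as.matrix(norm_expr[, lr$ligand, drop = FALSE])
  R <- as.matrix(norm_expr[, lr$receptor, drop = FALSE])
  L[ed$src, , drop = FALSE] * R[ed$tgt, , drop = FALSE]
}

.score_edges <- function(ed, V, strata, lr, source_stratum) {
  m <- strata[ed$src] == source_stratum
  if (!any(m) || !nrow(lr))
    return(data.frame(target = character(), ligand = character(),
                      receptor = character(), score = numeric(),
                      n_pairs = integer()))
  tgt <- strata[ed$tgt][m]
  sums <- rowsum(V[m, , drop = FALSE], tgt)
  cnt <- as.vector(table(tgt)[rownames(sums)])
  out <- data.frame(
    target = rep(rownames(sums), ncol(V)),
    ligand = rep(lr$ligand, each = nrow(sums)),
    receptor = rep(lr$receptor, each = nrow(sums)),
    score = as.vector(sums) / cnt,
    n_pairs = rep(cnt, ncol(V)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Permutation significance of ligand-receptor interaction scores
#'
#' The null re-draws cell labels (type and marker stratum jointly) by
#' permutation within each FOV, preserving the spatial point pattern and the
#' expression-cell linkage, and recomputes all scores N times. Empirical
#' p = (1 + #\{null >= observed\}) / (N + 1); a (target, LR) row missing from a
#' permutation contributes a null score of 0. P-values are BY-adjusted across
#' rows; a row is significant when adjusted p < alpha.
#'
#' @param pairs neighbor pairs from \code{\link{neighbor_pairs}}
#' @param norm_expr cells-by-genes normalized expression
#' @param strata per-cell stratum labels (named by cell id)
#' @param fov per-cell FOV ids, aligned with \code{strata}
#' @param lr_table data.frame(ligand, receptor)
#' @param source_stratum stratum acting as the source
#' @param params \code{\link{spatial_params}} (n_permutations >= 100, seed)
#' @return data.frame (class \code{interaction_result}): target, ligand,
#'   receptor, score, n_pairs, p, adj_p, significant; attribute
#'   \code{n_significant}
#' @export
permutation_significance <- function(pairs, norm_expr, strata, fov, lr_table,
                                     source_stratum, params = spatial_params()) {
  if (params$n_permutations < 100)
    stop("n_permutations must be at least 100")
  stopifnot(length(fov) == length(strata))
  obs <- lr_interaction_scores(pairs, norm_expr, strata, lr_table,
                               source_stratum, params)
  if (!nrow(obs)) {
    attr(obs, "n_significant") <- 0L
    class(obs) <- c("interaction_result", class(obs))
    return(obs)
  }
  ed <- .directed_edges(pairs, names(strata))
  lr <- .usable_lr(lr_table, colnames(norm_expr))
  V <- .edge_values(ed, norm_expr, lr)
  key <- paste(obs$target, obs$ligand, obs$receptor)
  ge <- integer(nrow(obs))
  lab <- unname(strata)
  fov <- as.character(fov)
  set.seed(params$seed)
  N <- params$n_permutations
  for (b in seq_len(N)) {
    perm <- stats::ave(seq_along(lab), fov, FUN = sample)
    sc <- .score_edges(ed, V, lab[perm], lr, source_stratum)
    null_score <- stats::setNames(rep(0, length(key)), key)
    if (nrow(sc)) {
      k2 <- paste(sc$target, sc$ligand, sc$receptor)
      hit <- k2 %in% key
      null_score[k2[hit]] <- sc$score[hit]
    }
    ge <- ge + (null_score >= obs$score)
  }
  obs$p <- (1 + ge) / (N + 1)
  obs$adj_p <- benjamini_yekutieli(obs$p)
  obs$significant <- obs$adj_p < params$alpha
  attr(obs, "n_significant") <- sum(obs$significant)
  class(obs) <- c("interaction_result", class(obs))
  obs
}

#' Group- and stratum-level interaction analysis
#'
#' Runs the marker-stratified permutation analysis separately within each
#' disease group, for both the marker-positive and marker-negative source
#' strata, and tallies significant interactions per (group, stratum) — the
#' quantity compared across groups in the study.
#'
#' @param counts \code{\link{count_matrix}} of raw counts (marker detection)
#' @param norm_expr normalized expression (same cells)
#' @param annotation \code{annotation_result} with refined labels
#' @param cells cell table
#' @param lr_table data.frame(ligand, receptor)
#' @param params \code{\link{spatial_params}}
#' @return list(results = per-row table with group and stratum columns,
#'   counts = data.frame(group, stratum, n_significant))
#' @export
interaction_analysis <- function(counts, norm_expr, annotation, cells,
                                 lr_table, params = spatial_params()) {
  strata_all <- marker_stratify(annotation, counts, params)
  keep <- annotation$retained & !is.na(strata_all)
  ids <- annotation$cell_id[keep]
  strata_all <- strata_all[ids]
  m <- match(ids, cells$cell_id)
  res_rows <- list(); cnt_rows <- list()
  for (g in intersect(c("IBD", "PD", "NHC"), unique(cells$group[m]))) {
    sel <- cells$group[m] == g
    sub_cells <- cells[m[sel], , drop = FALSE]
    prs <- neighbor_pairs(sub_cells, params$radius_um)
    for (sfx in c("+", "-")) {
      stratum <- paste0(params$source_type, "_", params$marker_gene, sfx)
      r <- permutation_significance(prs, norm_expr[ids[sel], , drop = FALSE],
                                    strata_all[sel], sub_cells$fov, lr_table,
                                    stratum, params)
      if (nrow(r)) {
        r$group <- g; r$stratum <- stratum
        res_rows[[length(res_rows) + 1L]] <- as.data.frame(r)
      }
      cnt_rows[[length(cnt_rows) + 1L]] <- data.frame(
        group = g, stratum = stratum,
        n_significant = attr(r, "n_significant"), stringsAsFactors = FALSE)
    }
  }
  list(results = if (length(res_rows)) do.call(rbind, res_rows) else NULL,
       counts = do.call(rbind, cnt_rows))
}

#' Edge table for a spatial connection map of one FOV
#'
#' Classifies each neighbor edge of a FOV for plotting: edges from a
#' source-type cell are colored by the marker status of the partner cell
#' (\code{to_marker_pos} / \code{to_marker_neg}); edges between two
#' non-source cells are \code{other}.
#'
#' @param pairs neighbor pairs from \code{\link{neighbor_pairs}}
#' @param strata per-cell stratum labels (named by cell id)
#' @param marker_pos named logical: raw marker detection per cell
#' @param fov FOV to export
#' @param params \code{\link{spatial_params}} (source type name)
#' @return data.frame: cell_i, cell_j, distance, class
#' @export
connection_map_export <- function(pairs, strata, marker_pos, fov,
                                  params = spatial_params()) {
  sub <- pairs[pairs$fov == fov, , drop = FALSE]
  pre <- paste0(params$source_type, "_", params$marker_gene)
  is_src <- function(id) startsWith(strata[id], pre)
  cls <- character(nrow(sub))
  for (k in seq_len(nrow(sub))) {
    i <- sub$cell_i[k]; j <- sub$cell_j[k]
    partner <- if (is_src(i)) j else if (is_src(j)) i else NA_character_
    cls[k] <- if (is.na(partner)) "other"
      else if (isTRUE(marker_pos[partner])) "to_marker_pos" else "to_marker_neg"
  }
  data.frame(cell_i = sub$cell_i, cell_j = sub$cell_j,
             distance = sub$distance, class = cls, stringsAsFactors = FALSE)
}
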