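# Shared in-code fixtures: a minimal cell table, hand-built QC slides with one
# planted violation per rule, and an annotation_result builder from labels.

make_cells <- function(n, fov = "f1", group = "NHC", patient = "p1",
                       area = NULL, x = NULL, y = NULL, ids = NULL) {
  data.frame(
    cell_id = if (is.null(ids)) sprintf("cell%03d", seq_len(n)) else ids,
    x_um = if (is.null(x)) seq_len(n) * 30 else x,
    y_um = if (is.null(y)) rep(0, n) else y,
    fov = fov, patient = patient, group = group,
    area = if (is.null(area)) rep(100, n) else area,
    stringsAsFactors = FALSE)
}

as_annotation <- function(cell_id, refined, retained = TRUE, posterior = 1) {
  out <- data.frame(cell_id = cell_id, label = refined, refined = refined,
                    posterior = posterior, retained = retained,
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_result", "data.frame")
  out
}

# RNA QC slide: 30 clean cells plus exactly one violation per rule.
# Panel: 40 genes + 20 negative probes so the two negative-probe rules can be
# violated independently.
make_qc_rna_slide <- function() {
  n_genes <- 40; n_np <- 20
  genes <- sprintf("G%02d", seq_len(n_genes))
  nps <- sprintf("NegPrb%02d", seq_len(n_np))
  base <- c(rep(2, n_genes), rep(0, n_np))          # 80 counts, 40 features
  rows <- list()
  for (i in 1:30) rows[[i]] <- base
  planted <- list()
  v <- function(gene_counts, np_counts, name) {
    rows[[length(rows) + 1L]] <<- c(gene_counts, np_counts)
    planted[[name]] <<- length(rows)
  }
  g <- function(per_gene) { x <- rep(0, n_genes); x[seq_along(per_gene)] <- per_gene; x }
  npv <- function(total) { x <- rep(0, n_np); if (total > 0) x[seq_len(total)] <- 1; x }
  v(g(rep(1.25, 12) * c(rep(2, 3), rep(1, 9))), npv(0), "low_counts")  # 15 counts, 12 feats
  v(g(rep(2, 36)), npv(8), "high_negprobe")        # 72 gene counts, 8/80 = 10%
  v(g(rep(1, 30)), npv(0), "counts_not_exceed_features")  # 30 counts = 30 feats
  v(g(rep(3, 9)), npv(0), "low_features")          # 27 counts over 9 feats
  v(c(rep(2, 35), rep(10, 5)), npv(10), "high_mean_neg")  # 120 genes, 10/20 = 0.5 mean
  v(g(rep(2, n_genes)), npv(0), "area_outlier")
  M <- do.call(rbind, rows)
  M[planted$low_counts, 1:3] <- 2; M[planted$low_counts, 4:12] <- 1  # exact ints
  dimnames(M) <- list(sprintf("cell%03d", seq_len(nrow(M))), c(genes, nps))
  set.seed(401)
  area <- runif(nrow(M), 90, 110)
  area[planted$area_outlier] <- 1000
  list(counts = count_matrix(M),
       cells = make_cells(nrow(M), area = area,
                          ids = rownames(M)),
       planted = planted)
}

# Protein QC slide: 20 clean cells (constant intensity 10 per protein, so
# every percentile ties at 10) plus one violation per rule.
make_qc_protein_slide <- function() {
  n_prot <- 30; n_np <- 2
  prots <- sprintf("P%02d", seq_len(n_prot))
  nps <- sprintf("NegPrb%02d", seq_len(n_np))
  base <- c(rep(10, n_prot), rep(5, n_np))
  rows <- replicate(20, base, simplify = FALSE)
  planted <- list()
  v <- function(prot, np, name) {
    rows[[length(rows) + 1L]] <<- c(prot, np)
    planted[[name]] <<- length(rows)
  }
  v(c(rep(9, 25), rep(10, 5)), c(5, 5), "insufficient_high")
  v(c(rep(100, 25), rep(10, 5)), c(5, 5), "insufficient_low")
  v(rep(10, n_prot), c(1.5, 1.5), "negprobe_window_lo")
  v(rep(10, n_prot), c(20, 20), "negprobe_window_hi")
  v(rep(10, n_prot), c(5, 5), "area_outlier")
  M <- do.call(rbind, rows)
  dimnames(M) <- list(sprintf("cell%03d", seq_len(nrow(M))), c(prots, nps))
  set.seed(402)
  area <- runif(nrow(M), 90, 110)
  area[planted$area_outlier] <- 1000
  list(intens = intensity_matrix(M),
       cells = make_cells(nrow(M), area = area, ids = rownames(M)),
       planted = planted)
}

# O(n^2) brute-force neighbor oracle, independent of the package's dist path
neighbor_oracle <- function(cells, r) {
  hits <- list()
  for (a in seq_len(nrow(cells) - 1)) for (b in (a + 1):nrow(cells)) {
    if (cells$fov[a] != cells$fov[b]) next
    d <- sqrt((cells$x_um[a] - cells$x_um[b])^2 + (cells$y_um[a] - cells$y_um[b])^2)
    if (d <= r) hits[[length(hits) + 1L]] <-
        data.frame(cell_i = cells$cell_id[a], cell_j = cells$cell_id[b],
                   distance = d, stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

pair_key <- function(p) sort(paste(pmin(p$cell_i, p$cell_j), pmax(p$cell_i, p$cell_j)))

# small cohort wrapper used across test files
tiny_cohort <- function(seed = 11L, n = c(IBD = 3L, PD = 3L, NHC = 3L),
                        cells_per_fov = 200L, ...) {
  simulate_cohort(sim_config(n_patients = n, cells_per_fov = cells_per_fov,
                             seed = seed, ...))
}

# run QC + annotation against truth-derived profiles; returns pieces used by
# downstream tests
annotate_cohort <- function(sim, gate = 0.75) {
  qc <- rna_cell_qc(sim$counts, sim$cells)
  k <- apply_qc(sim$counts, sim$cells, qc)
  clean <- exclude_genes(k$mat)
  truth <- sim$truth$cells
  m <- match(k$cells$cell_id, truth$cell_id)
  prof <- build_reference_profiles(clean$counts, truth$primary[m])
  ann1 <- annotate_cells(clean, prof, gate = gate)
  rp <- list()
  for (pt in unique(truth$primary[m])) {
    sel <- truth$primary[m] == pt
    rp[[pt]] <- build_reference_profiles(clean$counts[sel, , drop = FALSE],
                                         truth$refined[m][sel])
  }
  ann <- refine_subtypes(clean, ann1, rp, gate = gate)
  list(cells = k$cells, counts = k$mat, clean = clean,
       norm = normalize_rna(k$mat), annotation = ann,
       truth_primary = truth$primary[m], truth_refined = truth$refined[m],
       truth_marker = truth$marker_pos[m])
}
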