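#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (or load) -> RNA and protein QC -> normalization ->
#' reference-profile annotation (primary + refined, 0.75 posterior gate) ->
#' composition statistics -> differential expression (configured clusters) ->
#' optional gene-set ORA -> marker expression density -> marker-stratified
#' spatial ligand-receptor analysis -> fluid biomarkers -> report. Each stage
#' writes TSV outputs into \code{out_dir}; a manifest records the config,
#' seed, stage order and per-file MD5 hashes so a rerun can be verified
#' hash-identical.
#'
#' In simulate mode the reference profiles are built from a labeled training
#' split of the simulated cells (every 5th cell), standing in for the external
#' scRNA-seq reference object.
#'
#' @param config full or partial run configuration (merged over
#'   \code{\link{default_run_config}}); set \code{config$sim} to a
#'   \code{\link{sim_config}} or a list of \code{sim_config} overrides
#' @param stages subset of
#'   c("simulate","qc","annotate","stats","spatial","fluids","report")
#' @return list with stage outputs and \code{manifest}
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "qc", "annotate", "stats",
                                    "spatial", "fluids", "report")) {
  t0 <- Sys.time()
  cfg <- if (!is.null(config$..merged)) config else merge_config(config, quiet = TRUE)
  cfg$..merged <- TRUE
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!isTRUE(cfg$simulate)) {
    needed <- c("counts_path", "cells_path")
    miss <- needed[vapply(needed, function(k) is.null(cfg[[k]]), TRUE)]
    if (length(miss))
      stop("pre-flight: simulate=FALSE but config lacks ", paste(miss, collapse = ", "))
  }
  out <- list(config = cfg)
  stage_order <- character()
  emit <- function(df, name) {
    write_result_tsv(df, file.path(cfg$out_dir, name), seed = cfg$seed)
  }

  if ("simulate" %in% stages || isTRUE(cfg$simulate)) {
    sc <- if (inherits(cfg$sim, "sim_config")) cfg$sim else
      do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    sim <- simulate_cohort(sc)
    out$sim <- sim
    emit(sim$cells, "cells.tsv")
    emit(sim$truth$cells, "truth_cells.tsv")
    stage_order <- c(stage_order, "simulate")
  } else {
    out$sim <- list(counts = read_count_matrix(cfg$counts_path),
                    cells = read_cell_table(cfg$cells_path),
                    protein = NULL, truth = NULL)
  }

  if ("qc" %in% stages) {
    out$rna_qc <- rna_cell_qc(out$sim$counts, out$sim$cells, cfg$qc)
    emit(out$rna_qc$flags, "rna_qc_flags.tsv")
    kept <- apply_qc(out$sim$counts, out$sim$cells, out$rna_qc)
    out$counts_qc <- kept$mat
    out$cells_qc <- kept$cells
    out$norm <- normalize_rna(out$counts_qc)
    if (!is.null(out$sim$protein)) {
      out$protein_qc <- protein_cell_qc(out$sim$protein, out$sim$cells, cfg$qc)
      emit(out$protein_qc$flags, "protein_qc_flags.tsv")
      pk <- apply_qc(out$sim$protein, out$sim$cells, out$protein_qc)
      out$protein_norm <- normalize_protein(pk$mat, cfg$qc)
    }
    stage_order <- c(stage_order, "qc")
  }

  if ("annotate" %in% stages) {
    if (is.null(out$norm)) stop("annotate stage requires the qc stage")
    clean <- exclude_genes(out$counts_qc)
    truth <- out$sim$truth$cells
    m <- match(out$cells_qc$cell_id, truth$cell_id)
    train <- seq_len(nrow(out$cells_qc)) %% 5L == 0L
    ref_primary <- build_reference_profiles(
      clean$counts[train, , drop = FALSE], truth$primary[m][train])
    ann1 <- annotate_cells(clean, ref_primary, gate = cfg$qc$posterior_gate)
    refined_profiles <- list()
    for (pt in unique(truth$primary[m][train])) {
      sel <- train & truth$primary[m] == pt
      refined_profiles[[pt]] <- build_reference_profiles(
        clean$counts[sel, , drop = FALSE], truth$refined[m][sel])
    }
    out$annotation <- refine_subtypes(clean, ann1, refined_profiles,
                                      gate = cfg$qc$posterior_gate)
    emit(out$annotation, "annotation.tsv")
    stage_order <- c(stage_order, "annotate")
  }

  if ("stats" %in% stages) {
    if (is.null(out$annotation)) stop("stats stage requires the annotate stage")
    out$composition <- composition_test(out$annotation, out$cells_qc, cfg$stat)
    emit(out$composition, "composition.tsv")
    out$de <- list()
    for (cmp in c("IBD", "PD")) {
      de <- tryCatch(
        differential_expression(out$norm, out$annotation, out$cells_qc,
                                cluster = "colonocyte", comparison = cmp,
                                params = cfg$stat),
        error = function(e) { message("DE skipped (", cmp, "): ",
                                      conditionMessage(e)); NULL })
      if (!is.null(de)) {
        out$de[[cmp]] <- de
        emit(de, sprintf("de_colonocyte_%s_vs_NHC.tsv", cmp))
      }
    }
    if (!is.null(cfg$gmt_path) && length(out$de)) {
      sets <- read_gmt(cfg$gmt_path)
      out$ora <- lapply(out$de, function(de) {
        list(up = ora_enrichment(de$gene[de$category == "dark_red"], de$gene,
                                 sets, cfg$stat),
             down = ora_enrichment(de$gene[de$category == "dark_blue"], de$gene,
                                   sets, cfg$stat))
      })
    }
    out$density <- expression_density(out$counts_qc, out$annotation,
                                      out$cells_qc, cfg$spatial$marker_gene)
    emit(out$density$summary, "density_summary.tsv")
    stage_order <- c(stage_order, "stats")
  }

  if ("spatial" %in% stages) {
    if (is.null(out$annotation)) stop("spatial stage requires the annotate stage")
    lr <- if (!is.null(cfg$lr_path)) read_lr_table(cfg$lr_path) else
      data.frame(ligand = "CCL20", receptor = "CCR6", stringsAsFactors = FALSE)
    sp <- cfg$spatial
    sp$seed <- cfg$seed
    out$interactions <- interaction_analysis(out$counts_qc, out$norm,
                                             out$annotation, out$cells_qc,
                                             lr, sp)
    emit(out$interactions$counts, "interaction_counts.tsv")
    if (!is.null(out$interactions$results))
      emit(out$interactions$results, "interaction_results.tsv")
    stage_order <- c(stage_order, "spatial")
  }

  if ("fluids" %in% stages) {
    sc <- if (inherits(cfg$sim, "sim_config")) cfg$sim else
      do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    out$fluids <- list()
    for (mt in c("plasma", "stool")) {
      fp <- simulate_fluid_panel(sc, mt)
      pan <- fp$panel
      if (mt == "stool") pan <- normalize_stool(pan, sc$fluid$analytes)
      cmp <- lapply(c(IBD = "IBD", PD = "PD"), function(g)
        group_compare(pan, "CCL22", g, params = cfg$stat))
      fits <- lapply(c(IBD = "IBD", PD = "PD", NHC = "NHC"), function(g) {
        sub <- pan[pan$group == g, ]
        ols_fit(sub$CCL22, sub$ferritin)
      })
      dur <- {
        sub <- pan[pan$group == "PD", ]
        ols_fit(sub$disease_duration, sub$CCL22)
      }
      out$fluids[[mt]] <- list(panel = pan, compare = cmp,
                               ccl22_ferritin = fits, ccl22_duration = dur)
      emit(pan, sprintf("fluid_%s.tsv", mt))
    }
    stage_order <- c(stage_order, "fluids")
  }

  files <- sort(list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE))
  out$manifest <- list(
    tool = paste("mucosaSMI", as.character(utils::packageVersion("mucosaSMI"))),
    seed = cfg$seed,
    stages = stage_order,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    hashes = as.list(stats::setNames(unname(tools::md5sum(files)), basename(files))))
  yaml::write_yaml(out$manifest, file.path(cfg$out_dir, "manifest.yaml"))

  if ("report" %in% stages) {
    out$report_path <- report(out, file.path(cfg$out_dir, "report.md"))
    stage_order <- c(stage_order, "report")
  }
  invisible(out)
}

#' Write a markdown summary of pipeline outputs
#'
#' Summarizes whichever stages are present: QC pass fractions, the
#' composition table with significance codes, top volcano hits, top pathways
#' per direction, significant-interaction counts per group and stratum, and
#' fluid regressions. Regeneration from the same outputs is idempotent.
#'
#' @param outputs result list of \code{\link{run_pipeline}}
#' @param path output markdown path
#' @return \code{path}, invisibly
#' @export
report <- function(outputs, path) {
  if (all(vapply(outputs[c("rna_qc", "composition", "interactions", "fluids")],
                 is.null, TRUE)) && is.null(outputs$de))
    stop("no stage outputs to report")
  ln <- c("# mucosaSMI run report", "")
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")), "")
  }
  if (!is.null(outputs$rna_qc))
    ln <- c(ln, sprintf("RNA QC pass fraction: %.2f%%",
                        100 * outputs$rna_qc$summary$pass_fraction))
  if (!is.null(outputs$protein_qc))
    ln <- c(ln, sprintf("Protein QC pass fraction: %.2f%%",
                        100 * outputs$protein_qc$summary$pass_fraction))
  ln <- c(ln, "")
  if (!is.null(outputs$composition)) {
    ln <- c(ln, "## Cell-type composition (disease vs NHC)", "",
            fmt_tab(outputs$composition[, c("cluster", "comparison", "fc",
                                            "adj_p", "wilcoxon_p", "code")]))
  }
  if (length(outputs$de)) {
    for (cmp in names(outputs$de)) {
      de <- outputs$de[[cmp]]
      hits <- de[de$category != "ns", ]
      hits <- hits[order(hits$adj_p), ]
      ln <- c(ln, sprintf("## Top differential genes, colonocytes %s vs NHC", cmp),
              "", fmt_tab(utils::head(hits[, c("gene", "log2fc", "p", "adj_p",
                                               "category")], 10)))
    }
  }
  if (!is.null(outputs$ora)) {
    for (cmp in names(outputs$ora)) for (dir in c("up", "down")) {
      t10 <- top_pathways(outputs$ora[[cmp]][[dir]])
      if (nrow(t10))
        ln <- c(ln, sprintf("## Top pathways (%s, %s-regulated)", cmp, dir), "",
                fmt_tab(t10))
    }
  }
  if (!is.null(outputs$interactions)) {
    ln <- c(ln, "## Significant ligand-receptor interactions per group/stratum",
            "", fmt_tab(outputs$interactions$counts))
  }
  if (!is.null(outputs$fluids)) {
    for (mt in names(outputs$fluids)) {
      fl <- outputs$fluids[[mt]]
      ln <- c(ln, sprintf("## Fluid biomarkers (%s)", mt), "")
      for (g in names(fl$ccl22_ferritin)) {
        f <- fl$ccl22_ferritin[[g]]
        ln <- c(ln, sprintf("- CCL22 ~ ferritin, %s: R^2 = %.2f, p = %.3g (n = %d)",
                            g, f$r_squared, f$p, f$n))
      }
      ln <- c(ln, sprintf("- CCL22 ~ PD disease duration: R^2 = %.2f, p = %.3g",
                          fl$ccl22_duration$r_squared, fl$ccl22_duration$p))
      for (g in names(fl$compare))
        ln <- c(ln, sprintf("- CCL22 %s vs NHC: p = %.3g %s", g,
                            fl$compare[[g]]$p, fl$compare[[g]]$code))
      ln <- c(ln, "")
    }
  }
  writeLines(ln, path)
  invisible(path)
}
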