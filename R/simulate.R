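#' Synthetic-cohort configuration
#'
#' Defines the generative model of a CosMx-like RNA/protein cohort with known
#' ground truth. Defaults emulate the study conditions: 13 IBD / 12 PD / 8 NHC
#' participants, two 0.5 mm fields of view per participant, negative-binomial
#' gene counts with per-type reference profiles and lognormal size factors,
#' Poisson negative probes, lognormal cell areas with optional planted
#' outliers, Dirichlet per-patient compositions with disease multipliers
#' (colonocytes enriched in IBD and PD, CD4 T cells depleted in IBD, CD8 T
#' cells enriched in PD), planted differential expression (FTH1 up in IBD
#' colonocytes and down in PD, ferroportin SLC40A1 down in both), an
#' FTH1-high/low mixture defining marker-positive colonocytes, and — in the
#' disease groups — ligand up-regulation in marker-positive colonocytes plus
#' parent-offspring spatial attraction of plasma cells toward them.
#'
#' @param n_patients named integer vector of participants per group
#' @param fovs_per_patient fields of view per participant
#' @param fov_size_um side length of the square FOV, micrometres
#' @param cells_per_fov cells per FOV (the study totals 75,170 cells over 66
#'   FOVs, ~1100/FOV; the default is a working-size choice, not a study value)
#' @param type_hierarchy named list primary type -> refined subtype names
#' @param base_composition Dirichlet mean over refined types (sums to 1)
#' @param composition_multipliers list group -> named multipliers on the mean
#' @param dirichlet_conc Dirichlet concentration (patient-to-patient spread)
#' @param profiles genes x refined-types matrix of expected counts per cell at
#'   size factor 1; \code{NULL} uses the built-in colon panel
#' @param expression_scale global multiplier on all profile rates
#' @param de_effects list group -> refined type -> named fold changes
#' @param nb_dispersion NB dispersion (variance = mean + mean^2 * dispersion)
#' @param size_factor_sdlog lognormal sd of per-cell size factors
#' @param negprobe_n,negprobe_rate number of negative probes and their
#'   Poisson mean count per cell
#' @param area_meanlog,area_sdlog lognormal cell-area parameters (um^2)
#' @param planted_outlier_fraction fraction of cells whose area is multiplied
#'   by 10 (recorded in truth)
#' @param marker list(gene, source_type, pos_frac, pos_mult, neg_mult): the
#'   high/low marker mixture within the source type; positivity is the truth
#'   of having drawn the high component
#' @param marker_linked list(genes = named multipliers, groups): extra
#'   expression applied to marker-positive source cells in those groups
#' @param attraction list(target_type, strength, range_um, groups): each
#'   target-type cell is, with probability \code{strength}, re-placed within
#'   \code{range_um} of a random marker-positive source cell of its FOV
#' @param protein list(n_broad, n_sparse_per_type, sparse_frac, broad_meanlog,
#'   sparse_meanlog, sdlog, cell_sdlog, negprobe_n, negprobe_meanlog,
#'   negprobe_sdlog): lognormal protein intensity model
#' @param fluid fluid-panel block, see \code{\link{simulate_fluid_panel}}
#' @param seed RNG seed
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_patients = c(IBD = 13L, PD = 12L, NHC = 8L),
                       fovs_per_patient = 2L,
                       fov_size_um = 500,
                       cells_per_fov = 1200L,
                       type_hierarchy = list(
                         epithelial = c("colonocyte", "goblet"),
                         myeloid = c("M2_macrophage", "neutrophil"),
                         plasma = c("IgA_plasma"),
                         stroma = c("myofibroblast"),
                         tcell = c("CD4_T", "CD8_T")),
                       base_composition = c(colonocyte = 0.20, goblet = 0.12,
                                            M2_macrophage = 0.10, neutrophil = 0.08,
                                            IgA_plasma = 0.18, myofibroblast = 0.12,
                                            CD4_T = 0.12, CD8_T = 0.08),
                       composition_multipliers = list(
                         IBD = c(colonocyte = 2, CD4_T = 0.5),
                         PD = c(colonocyte = 2, CD8_T = 2)),
                       dirichlet_conc = 100,
                       profiles = NULL,
                       expression_scale = 1,
                       de_effects = list(
                         IBD = list(colonocyte = c(FTH1 = 2, SLC40A1 = 0.5)),
                         PD = list(colonocyte = c(FTH1 = 0.5, SLC40A1 = 0.5))),
                       nb_dispersion = 0.3,
                       size_factor_sdlog = 0.3,
                       negprobe_n = 10L,
                       negprobe_rate = 0.02,
                       area_meanlog = log(120),
                       area_sdlog = 0.35,
                       planted_outlier_fraction = 0,
                       marker = list(gene = "FTH1", source_type = "colonocyte",
                                     pos_frac = 0.5, pos_mult = 4, neg_mult = 0.02),
                       marker_linked = list(genes = c(CCL20 = 12),
                                            groups = c("IBD", "PD")),
                       attraction = list(target_type = "IgA_plasma",
                                         strength = 0, range_um = 25,
                                         groups = c("IBD", "PD")),
                       protein = list(n_broad = 6L, n_sparse_per_type = 5L,
                                      sparse_frac = 0.3,
                                      broad_meanlog = log(20),
                                      sparse_meanlog = log(15), sdlog = 0.5,
                                      cell_sdlog = 0.3, negprobe_n = 2L,
                                      negprobe_meanlog = log(6),
                                      negprobe_sdlog = 0.2),
                       fluid = list(
                         n = c(IBD = 15L, PD = 14L, NHC = 10L),
                         analytes = c("Eotaxin", "Eotaxin3", "IFNg", "IL1b",
                                      "IL6", "IL8", "CCL22", "TNFa", "ferritin"),
                         meanlog = c(CCL22 = log(400), ferritin = log(50)),
                         group_shift = list(PD = c(CCL22 = log(0.5))),
                         sdlog = 0.5,
                         rho = c(IBD = 0.77, PD = 0.71, NHC = 0),
                         duration_range = c(2, 15),
                         duration_r2 = 0.32),
                       seed = 1L) {
  refined <- unlist(type_hierarchy, use.names = FALSE)
  stopifnot(setequal(names(base_composition), refined),
            abs(sum(base_composition) - 1) < 1e-8,
            all(base_composition > 0),
            negprobe_rate >= 0, nb_dispersion >= 0,
            fov_size_um > 2 * attraction$range_um)
  if (any(vapply(fluid$rho, function(r) abs(r) >= 1, TRUE)))
    stop("fluid correlation |rho| must be < 1")
  structure(as.list(environment())[names(formals(sim_config))],
            class = c("sim_config", "list"))
}

# built-in colon panel: marker blocks per refined type, housekeeping genes
# shared equally, iron axis (FTH1 / SLC40A1), a chemokine ligand-receptor
# axis (CCL20 -> CCR6), immunoglobulins (to exercise Ig exclusion) and the
# study's spike-in genes at a low uniform rate
.default_profiles <- function(hierarchy) {
  refined <- unlist(hierarchy, use.names = FALSE)
  markers <- list(
    colonocyte = c("CEACAM7", "CA2", "AQP8", "GUCA2A", "MS4A12"),
    goblet = c("MUC2", "TFF3", "ZG16", "SPINK4", "FCGBP"),
    M2_macrophage = c("CD163", "MRC1", "MSR1", "C1QA", "C1QB"),
    neutrophil = c("S100A8", "S100A9", "FCGR3B", "CSF3R", "CXCR2"),
    IgA_plasma = c("JCHAIN", "MZB1", "DERL3", "XBP1", "PRDM1"),
    myofibroblast = c("ACTA2", "TAGLN", "MYL9", "COL1A1", "PDGFRB"),
    CD4_T = c("CD4", "IL7R", "CCR7", "CD40LG", "TCF7"),
    CD8_T = c("CD8A", "CD8B", "GZMK", "NKG7", "CCL5"))
  markers <- markers[refined]
  housekeeping <- c("ACTB", "GAPDH", "B2M", "RPL13A", "HPRT1", "TUBB")
  spike <- c("SLC6A4", "CHGA", "SLC11A2", "HAMP", "IREB2", "ITPKB",
             "NDUFB1", "PINK1", "PYY", "RAB8A", "TF")
  genes <- c(unlist(markers, use.names = FALSE), housekeeping,
             "FTH1", "SLC40A1", "CCL20", "CCR6", "IGHA1", "IGKC", spike)
  P <- matrix(0.1, length(genes), length(refined),
              dimnames = list(genes, refined))
  for (t in refined) P[markers[[t]], t] <- 8
  P[housekeeping, ] <- 5
  P["FTH1", ] <- 0.3
  # base rate before the marker high/low mixture (x4 in marker-positive
  # cells): positives sit near 5 counts/cell, where log1p is near-linear
  P["FTH1", "colonocyte"] <- 1.2
  P["SLC40A1", ] <- 0.2
  P["SLC40A1", c("colonocyte", "M2_macrophage")] <- 2
  # CCL20 is an inducible chemokine: near-silent in healthy mucosa, strongly
  # induced in marker-positive colonocytes of the disease groups (marker_linked)
  P["CCL20", ] <- 0.05
  P["CCL20", "colonocyte"] <- 0.1
  P["CCR6", ] <- 0.2
  P["CCR6", c("IgA_plasma", "CD4_T", "CD8_T")] <- 3
  P[c("IGHA1", "IGKC"), ] <- 6       # Igs high in every type
  P[spike, ] <- 0.2
  P
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) stop("infeasible composition: zero-sum Dirichlet draw")
  x / sum(x)
}

# counts ~ NB(mu, dispersion); dispersion 0 reduces to Poisson
.rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a CosMx-like spatial cohort with known ground truth
#'
#' @param config \code{\link{sim_config}}
#' @return list: \code{counts} (\code{count_matrix}, genes + negative probes),
#'   \code{cells} (cell table with morphology means), \code{protein}
#'   (\code{intensity_matrix}), \code{truth} (list: cells data.frame with true
#'   primary/refined labels and marker status, de_effects, composition per
#'   patient, planted outlier ids). Deterministic given \code{config$seed}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  hierarchy <- config$type_hierarchy
  refined <- unlist(hierarchy, use.names = FALSE)
  primary_of <- stats::setNames(rep(names(hierarchy), lengths(hierarchy)), refined)
  P <- if (is.null(config$profiles)) .default_profiles(hierarchy) else config$profiles
  stopifnot(all(refined %in% colnames(P)))
  P <- P[, refined, drop = FALSE] * config$expression_scale
  genes <- rownames(P)

  groups <- rep(names(config$n_patients), config$n_patients)
  patients <- unlist(lapply(names(config$n_patients), function(g)
    sprintf("%s_p%02d", g, seq_len(config$n_patients[[g]]))))

  base <- config$base_composition[refined]
  comp_rows <- list(); cell_rows <- list()
  for (pi in seq_along(patients)) {
    g <- groups[pi]
    mean_comp <- base
    mult <- config$composition_multipliers[[g]]
    if (!is.null(mult)) mean_comp[names(mult)] <- mean_comp[names(mult)] * mult
    mean_comp <- mean_comp / sum(mean_comp)
    comp <- .rdirichlet(mean_comp * config$dirichlet_conc)
    comp_rows[[pi]] <- data.frame(patient = patients[pi], group = g,
                                  type = refined, proportion = comp)
    for (fi in seq_len(config$fovs_per_patient)) {
      n <- config$cells_per_fov
      typ <- sample(refined, n, replace = TRUE, prob = comp)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        patient = patients[pi], group = g,
        fov = sprintf("%s_f%d", patients[pi], fi),
        refined = typ, primary = unname(primary_of[typ]),
        x_um = stats::runif(n, 0, config$fov_size_um),
        y_um = stats::runif(n, 0, config$fov_size_um),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cell_rows)
  cells$cell_id <- sprintf("c%06d", seq_len(nrow(cells)))

  # marker truth: high/low mixture membership within the source type
  mk <- config$marker
  cells$marker_pos <- FALSE
  src <- cells$refined == mk$source_type
  cells$marker_pos[src] <- stats::runif(sum(src)) < mk$pos_frac

  # parent-offspring attraction: re-place target cells near marker-positive
  # sources within the same FOV
  att <- config$attraction
  if (att$strength > 0) {
    for (f in unique(cells$fov)) {
      in_f <- cells$fov == f
      if (!cells$group[in_f][1] %in% att$groups) next
      parents <- which(in_f & cells$marker_pos)
      if (!length(parents)) next
      targets <- which(in_f & cells$refined == att$target_type)
      move <- targets[stats::runif(length(targets)) < att$strength]
      if (!length(move)) next
      par <- parents[sample.int(length(parents), length(move), replace = TRUE)]
      r <- att$range_um * sqrt(stats::runif(length(move)))
      th <- stats::runif(length(move), 0, 2 * pi)
      cells$x_um[move] <- pmin(pmax(cells$x_um[par] + r * cos(th), 0), config$fov_size_um)
      cells$y_um[move] <- pmin(pmax(cells$y_um[par] + r * sin(th), 0), config$fov_size_um)
    }
  }

  # per-cell gene rates: profile x planted DE x marker mixture x
  # marker-linked ligand boost, then lognormal size factor
  rates <- t(P[, cells$refined, drop = FALSE])  # cells x genes
  for (g in names(config$de_effects)) {
    for (t in names(config$de_effects[[g]])) {
      eff <- config$de_effects[[g]][[t]]
      sel <- cells$group == g & cells$refined == t
      if (!any(sel)) next
      for (gene in names(eff)) {
        if (gene %in% genes) rates[sel, gene] <- rates[sel, gene] * eff[[gene]]
      }
    }
  }
  if (mk$gene %in% genes) {
    pos <- src & cells$marker_pos
    neg <- src & !cells$marker_pos
    rates[pos, mk$gene] <- rates[pos, mk$gene] * mk$pos_mult
    rates[neg, mk$gene] <- rates[neg, mk$gene] * mk$neg_mult
  }
  ml <- config$marker_linked
  if (length(ml$genes)) {
    boosted <- src & cells$marker_pos & cells$group %in% ml$groups
    for (gene in names(ml$genes)) {
      if (gene %in% genes) rates[boosted, gene] <- rates[boosted, gene] * ml$genes[[gene]]
    }
  }
  sf <- stats::rlnorm(nrow(cells), 0, config$size_factor_sdlog)
  mu <- rates * sf
  X <- matrix(.rcounts(length(mu), as.vector(mu), config$nb_dispersion),
              nrow(cells), length(genes), dimnames = list(cells$cell_id, genes))

  npn <- config$negprobe_n
  NP <- matrix(stats::rpois(nrow(cells) * npn, config$negprobe_rate),
               nrow(cells), npn,
               dimnames = list(cells$cell_id, sprintf("NegPrb%03d", seq_len(npn))))
  counts <- count_matrix(cbind(X, NP))

  # areas with planted x10 outliers
  cells$area <- stats::rlnorm(nrow(cells), config$area_meanlog, config$area_sdlog)
  out_ids <- character()
  if (config$planted_outlier_fraction > 0) {
    k <- max(1L, round(config$planted_outlier_fraction * nrow(cells)))
    oi <- sample.int(nrow(cells), k)
    cells$area[oi] <- cells$area[oi] * 10
    out_ids <- cells$cell_id[oi]
  }

  # morphology-marker means: separated by primary type with Gaussian noise
  morph_mu <- rbind(
    epithelial = c(dapi = 200, panck = 150, cd45 = 10, cd3 = 5, cd68 = 5),
    myeloid    = c(dapi = 180, panck = 10, cd45 = 120, cd3 = 10, cd68 = 140),
    plasma     = c(dapi = 190, panck = 10, cd45 = 130, cd3 = 10, cd68 = 10),
    stroma     = c(dapi = 170, panck = 15, cd45 = 15, cd3 = 5, cd68 = 10),
    tcell      = c(dapi = 185, panck = 10, cd45 = 140, cd3 = 120, cd68 = 8))
  mm <- morph_mu[cells$primary, , drop = FALSE]
  noise <- matrix(stats::rnorm(length(mm), 0, 15), nrow(mm))
  mm <- pmax(mm + noise, 0)
  cells$mean_dapi <- mm[, "dapi"]; cells$mean_panck <- mm[, "panck"]
  cells$mean_cd45 <- mm[, "cd45"]; cells$mean_cd3 <- mm[, "cd3"]
  cells$mean_cd68 <- mm[, "cd68"]

  protein <- .simulate_protein(cells, names(hierarchy), config$protein)

  truth <- list(
    cells = cells[, c("cell_id", "patient", "group", "fov", "primary",
                      "refined", "marker_pos")],
    de_effects = config$de_effects,
    composition = do.call(rbind, comp_rows),
    planted_area_outliers = out_ids,
    marker = mk)

  cells_out <- cells[, c("cell_id", "x_um", "y_um", "fov", "patient", "group",
                         "area", "mean_dapi", "mean_panck", "mean_cd45",
                         "mean_cd3", "mean_cd68")]
  rownames(cells_out) <- NULL
  list(counts = counts, cells = validate_cell_table(cells_out),
       protein = protein, truth = truth)
}

# lognormal protein intensities: broad channels in every cell, sparse
# (checkpoint-like) channels expressed in a fraction of one primary type,
# negative-probe channels at background, all scaled by a per-cell factor.
# Sparse channels leave most cells at zero, which creates percentile ties
# that make the published keep-rules behave sensibly.
.simulate_protein <- function(cells, primaries, pc) {
  n <- nrow(cells)
  broad <- sprintf("Broad%02d", seq_len(pc$n_broad))
  sparse <- unlist(lapply(primaries, function(p)
    sprintf("%s_mk%d", p, seq_len(pc$n_sparse_per_type))))
  cf <- stats::rlnorm(n, 0, pc$cell_sdlog)
  B <- matrix(stats::rlnorm(n * length(broad), pc$broad_meanlog, pc$sdlog),
              n, length(broad), dimnames = list(cells$cell_id, broad))
  S <- matrix(0, n, length(sparse), dimnames = list(cells$cell_id, sparse))
  owner <- rep(primaries, each = pc$n_sparse_per_type)
  for (k in seq_along(sparse)) {
    expr <- cells$primary == owner[k] & stats::runif(n) < pc$sparse_frac
    S[expr, k] <- stats::rlnorm(sum(expr), pc$sparse_meanlog, pc$sdlog)
  }
  NP <- matrix(stats::rlnorm(n * pc$negprobe_n, pc$negprobe_meanlog, pc$negprobe_sdlog),
               n, pc$negprobe_n,
               dimnames = list(cells$cell_id, sprintf("NegPrb%02d", seq_len(pc$negprobe_n))))
  intensity_matrix(cbind(B, S, NP) * cf)
}
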