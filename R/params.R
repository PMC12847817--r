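#' Quality-control parameters
#'
#' All per-cell QC thresholds for the RNA and protein panels. Defaults are the
#' study values: cells are flagged when total gene counts fall below 20, when
#' 10% or more of counts come from negative probes, when total counts do not
#' exceed the number of detected genes, when fewer than 10 features are
#' detected, when the mean raw count per negative probe reaches 0.5, or when
#' the cell area is a Grubbs outlier at p = 0.01 within its FOV. Protein cells
#' are kept when at least half of the proteins sit at or above their 90th
#' percentile, at least 10 proteins sit at or below their 50th percentile, and
#' the mean negative-probe intensity lies in the 2-15 window.
#'
#' @param rna_min_counts minimum total gene counts per cell
#' @param rna_max_negprobe_frac maximal tolerated negative-probe count fraction
#' @param rna_min_features minimum number of detected gene features
#' @param rna_mean_neg_max flag threshold on the mean raw count per negative probe
#' @param rna_counts_include_negprobes whether negative-probe counts enter the
#'   \code{rna_min_counts} total (the vendor convention is ambiguous; default
#'   excludes them as they are noise, not signal)
#' @param grubbs_alpha significance level of the iterative Grubbs area test
#' @param grubbs_scope \code{"fov"} (default) or \code{"slide"}: grouping
#'   within which areas are tested
#' @param posterior_gate posterior-probability gate consumed by the annotation
#'   stage (cells below it are dropped from downstream analysis)
#' @param prot_high_pct,prot_high_frac keep rule: at least \code{prot_high_frac}
#'   of proteins at or above their \code{prot_high_pct}-th percentile
#' @param prot_low_pct,prot_min_low keep rule: at least \code{prot_min_low}
#'   proteins at or below their \code{prot_low_pct}-th percentile
#' @param prot_high_scope \code{"per_protein"} (default; percentile of each
#'   protein across cells) or \code{"per_cell"} (percentile within the cell's
#'   own protein vector) — the published wording admits both readings
#' @param prot_neg_lo,prot_neg_hi acceptance window on the mean negative-probe
#'   intensity
#' @param arcsinh_cofactor cofactor of the arcsinh protein transform
#' @return list of class \code{qc_params}
#' @export
qc_params <- function(rna_min_counts = 20L,
                      rna_max_negprobe_frac = 0.10,
                      rna_min_features = 10L,
                      rna_mean_neg_max = 0.5,
                      rna_counts_include_negprobes = FALSE,
                      grubbs_alpha = 0.01,
                      grubbs_scope = c("fov", "slide"),
                      posterior_gate = 0.75,
                      prot_high_pct = 90,
                      prot_high_frac = 0.50,
                      prot_low_pct = 50,
                      prot_min_low = 10L,
                      prot_high_scope = c("per_protein", "per_cell"),
                      prot_neg_lo = 2,
                      prot_neg_hi = 15,
                      arcsinh_cofactor = 50) {
  grubbs_scope <- match.arg(grubbs_scope)
  prot_high_scope <- match.arg(prot_high_scope)
  stopifnot(grubbs_alpha > 0, grubbs_alpha < 1,
            rna_min_counts > 0, rna_min_features > 0,
            prot_high_pct > 0, prot_high_pct < 100,
            prot_low_pct > 0, prot_low_pct < 100,
            prot_min_low > 0, posterior_gate >= 0, posterior_gate <= 1,
            arcsinh_cofactor > 0, prot_neg_lo <= prot_neg_hi)
  structure(as.list(environment()), class = c("qc_params", "list"))
}

#' Statistical parameters for composition, differential expression and ORA
#'
#' @param fc_enrich,fc_deplete fold-change gates on composition significance
#'   codes (a cluster is starred only when FC > 1.5 or FC < 0.66)
#' @param de_fc_up,de_fc_down volcano fold-change thresholds (1.2 / 0.83)
#' @param alpha significance level on adjusted p-values
#' @param star_levels adjusted-p cut points mapped to significance codes
#' @param mtc multiple-testing correction; Benjamini-Yekutieli throughout
#' @param top_k_pathways pathways reported per direction in ORA
#' @param de_min_cells minimum cells per arm for a cluster to be tested
#' @param de_eps pseudo-expression added to both means in the DE fold change
#' @param chi2_correction apply Yates continuity correction in the 2x2 test
#' @return list of class \code{stat_params}
#' @export
stat_params <- function(fc_enrich = 1.5, fc_deplete = 0.66,
                        de_fc_up = 1.2, de_fc_down = 0.83,
                        alpha = 0.05,
                        star_levels = c("*" = 0.05, "**" = 0.01, "***" = 0.001),
                        mtc = "BY",
                        top_k_pathways = 10L,
                        de_min_cells = 20L,
                        de_eps = 1e-9,
                        chi2_correction = FALSE) {
  stopifnot(fc_deplete < 1, fc_enrich > 1, alpha > 0, alpha < 1,
            de_fc_down < 1, de_fc_up > 1)
  structure(as.list(environment()), class = c("stat_params", "list"))
}

#' Spatial interaction parameters
#'
#' @param radius_um neighborhood radius in micrometres (closed ball); all
#'   cell-cell communication is scored within this distance inside a FOV
#' @param marker_gene gene whose raw detection stratifies the source type
#' @param marker_min_count raw counts at or above which a cell is marker-positive
#' @param source_type refined cell type to stratify (the signal-sending type)
#' @param n_permutations label permutations for the empirical null
#' @param perm_scope permutation scope; labels are shuffled within FOV
#' @param alpha significance level on BY-adjusted empirical p-values
#' @param mtc multiple-testing correction
#' @param seed RNG seed of the permutation stream
#' @param um_per_px optional scale factor applied to coordinates given in pixels
#' @return list of class \code{spatial_params}
#' @export
spatial_params <- function(radius_um = 25, marker_gene = "FTH1",
                           marker_min_count = 1L, source_type = "colonocyte",
                           n_permutations = 1000L, perm_scope = "fov",
                           alpha = 0.05, mtc = "BY", seed = 1L,
                           um_per_px = NULL) {
  stopifnot(radius_um > 0, marker_min_count >= 1, n_permutations >= 100)
  structure(as.list(environment()), class = c("spatial_params", "list"))
}
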