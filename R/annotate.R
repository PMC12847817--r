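#' Remove features from a count matrix by symbol or prefix
#'
#' Default behaviour removes immunoglobulin genes (IGH*/IGK*/IGL* prefixes),
#' which are highly expressed across all cell types and would dominate the
#' annotation likelihood.
#'
#' @param counts \code{\link{count_matrix}}
#' @param symbols exact feature names to remove (optional)
#' @param prefixes name prefixes to remove; default the Ig loci
#' @return \code{count_matrix} without those features; cells unchanged
#' @export
exclude_genes <- function(counts, symbols = NULL, prefixes = c("IGH", "IGK", "IGL")) {
  feats <- colnames(counts$counts)
  drop <- feats %in% symbols
  for (p in prefixes) drop <- drop | startsWith(feats, p)
  if (all(drop | counts$negprobe_mask) && any(!counts$negprobe_mask))
    stop("exclusion would remove all gene features")
  if (all(drop)) stop("exclusion would remove all features")
  counts$counts <- counts$counts[, !drop, drop = FALSE]
  counts$negprobe_mask <- counts$negprobe_mask[!drop]
  counts
}

#' Build reference expression profiles from labeled counts
#'
#' Per type, the profile is the pseudocount-smoothed fraction of that type's
#' total counts carried by each gene: (sum of counts + pseudocount) /
#' normalizing constant, so each profile sums to 1 over genes. Profiles stand
#' in for an external labeled scRNA-seq reference.
#'
#' @param counts \code{\link{count_matrix}} (genes only are used) or a plain
#'   cells-by-genes matrix
#' @param labels character vector of cell labels, one per cell
#' @param pseudocount smoothing constant keeping profiles strictly positive
#' @return genes-by-types matrix of class \code{reference_profiles}; columns
#'   sum to 1
#' @export
build_reference_profiles <- function(counts, labels, pseudocount = 1e-6) {
  m <- if (inherits(counts, "count_matrix")) gene_counts(counts) else counts
  stopifnot(length(labels) == nrow(m))
  types <- sort(unique(labels))
  P <- vapply(types, function(t) {
    s <- Matrix::colSums(m[labels == t, , drop = FALSE])
    if (sum(s) == 0) stop("label with zero total counts: ", t)
    s <- s + pseudocount
    s / sum(s)
  }, numeric(ncol(m)))
  rownames(P) <- colnames(m)
  structure(P, class = c("reference_profiles", class(P)))
}

# per-cell log-likelihood matrix (cells x types) under the count model.
# Poisson: ll_t = sum_g x_g log(n p_tg) - n p_tg; the terms sum_g x_g log(n)
# and sum_g n p_tg = n are constant across types and dropped.
# dispersion > 0 switches to NB with size 1/dispersion.
.type_loglik <- function(X, P, libsize, dispersion = 0) {
  if (dispersion <= 0) {
    as.matrix(X %*% log(P))
  } else {
    k <- 1 / dispersion
    ll <- matrix(0, nrow(X), ncol(P), dimnames = list(rownames(X), colnames(P)))
    Xd <- as.matrix(X)
    for (t in seq_len(ncol(P))) {
      mu <- outer(libsize, P[, t])
      ll[, t] <- rowSums(k * log(k / (k + mu)) + Xd * log(mu / (k + mu)))
    }
    ll
  }
}

#' Supervised posterior cell-type annotation
#'
#' Each cell is scored under every candidate type by a Poisson count model
#' with the cell's library size as exposure and the reference profile as rate
#' (optionally negative-binomial via \code{dispersion}); optional
#' morphology-marker means enter as independent Gaussian features. Posteriors
#' are the prior-weighted normalized likelihoods; a cell is retained only when
#' its best posterior reaches the gate (0.75 in the study).
#'
#' @param counts \code{\link{count_matrix}} of QC-passing, Ig-excluded cells
#' @param profiles \code{\link{reference_profiles}} (genes x types)
#' @param prior prior over types; uniform when \code{NULL}
#' @param gate posterior-probability retention gate
#' @param dispersion optional NB dispersion (0 = Poisson)
#' @param morphology optional cells-by-markers matrix of morphology means
#' @param morph_params optional list(mean, sd): per-type marker means/sds
#'   (types x markers matrices) learned from a labeled reference
#' @return data.frame (class \code{annotation_result}) with cell_id, label,
#'   posterior, retained; posteriors over candidate types sum to 1 per cell
#' @export
annotate_cells <- function(counts, profiles, prior = NULL, gate = 0.75,
                           dispersion = 0, morphology = NULL, morph_params = NULL) {
  if (ncol(profiles) < 1) stop("no candidate types")
  g <- if (inherits(counts, "count_matrix")) gene_counts(counts) else counts
  genes <- intersect(rownames(profiles), colnames(g))
  if (!length(genes)) stop("no overlap between profile genes and panel")
  X <- g[, genes, drop = FALSE]
  P <- profiles[genes, , drop = FALSE]
  P <- sweep(P, 2, colSums(P), `/`)       # renormalize to the shared gene set
  lib <- Matrix::rowSums(X)
  ll <- .type_loglik(X, P, lib, dispersion)
  if (!is.null(morphology) && !is.null(morph_params)) {
    stopifnot(nrow(morphology) == nrow(ll))
    for (t in colnames(P)) {
      mu <- morph_params$mean[t, colnames(morphology)]
      sd <- morph_params$sd[t, colnames(morphology)]
      ll[, t] <- ll[, t] + rowSums(stats::dnorm(morphology,
        mean = matrix(mu, nrow(morphology), ncol(morphology), byrow = TRUE),
        sd = matrix(sd, nrow(morphology), ncol(morphology), byrow = TRUE),
        log = TRUE))
    }
  }
  if (is.null(prior)) prior <- rep(1 / ncol(P), ncol(P))
  ll <- sweep(ll, 2, log(prior), `+`)
  # softmax with log-sum-exp stabilization
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  best <- max.col(post, ties.method = "first")
  out <- data.frame(cell_id = rownames(g),
                    label = colnames(P)[best],
                    posterior = post[cbind(seq_len(nrow(post)), best)],
                    retained = post[cbind(seq_len(nrow(post)), best)] >= gate,
                    stringsAsFactors = FALSE)
  attr(out, "posterior_matrix") <- post
  class(out) <- c("annotation_result", "data.frame")
  out
}

#' Refine retained cells into subtypes within each primary class
#'
#' Within each retained primary class, the same posterior classifier is re-run
#' against that class's refined profiles with the same gate (e.g., T cells
#' parsed into CD4 and CD8). Classes without refined profiles carry the
#' primary label and posterior over.
#'
#' @param counts \code{\link{count_matrix}} used for primary annotation
#' @param annotation \code{annotation_result} from \code{\link{annotate_cells}}
#' @param refined_profiles named list: primary type -> reference_profiles of
#'   its subtypes
#' @param gate posterior gate applied at the refined tier
#' @param dispersion optional NB dispersion
#' @return data.frame with cell_id, primary, primary_posterior, refined,
#'   refined_posterior, retained (both tiers gated); non-retained primary
#'   cells have NA refined labels
#' @export
refine_subtypes <- function(counts, annotation, refined_profiles, gate = 0.75,
                            dispersion = 0) {
  out <- data.frame(cell_id = annotation$cell_id,
                    primary = annotation$label,
                    primary_posterior = annotation$posterior,
                    refined = NA_character_,
                    refined_posterior = NA_real_,
                    retained = FALSE,
                    stringsAsFactors = FALSE)
  g <- if (inherits(counts, "count_matrix")) counts else count_matrix(counts)
  for (cls in unique(annotation$label[annotation$retained])) {
    idx <- which(annotation$label == cls & annotation$retained)
    if (cls %in% names(refined_profiles)) {
      sub <- g
      sub$counts <- sub$counts[idx, , drop = FALSE]
      ann <- annotate_cells(sub, refined_profiles[[cls]], gate = gate,
                            dispersion = dispersion)
      out$refined[idx] <- ann$label
      out$refined_posterior[idx] <- ann$posterior
      out$retained[idx] <- ann$retained
    } else {
      out$refined[idx] <- cls
      out$refined_posterior[idx] <- annotation$posterior[idx]
      out$retained[idx] <- TRUE
    }
  }
  class(out) <- c("annotation_result", "data.frame")
  out
}
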