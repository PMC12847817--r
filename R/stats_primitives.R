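#' Benjamini-Yekutieli adjusted p-values
#'
#' FDR step-up procedure valid under arbitrary dependence: the BH adjustment
#' inflated by the harmonic sum c(m) = sum_{k=1..m} 1/k, i.e.
#' adj_(i) = min_{j >= i}( m c(m) p_(j) / j ) capped at 1, returned in the
#' original order.
#'
#' @param pvals numeric vector of p-values between 0 and 1
#' @return adjusted p-values, same length and order
#' @export
benjamini_yekutieli <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BY")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param table 2x2 non-negative integer matrix; all margins must be positive
#' @param correction apply the Yates continuity correction (default off: cell
#'   counts in this pipeline are in the thousands, where it is immaterial)
#' @return list(statistic, p) — chi-squared with 1 df
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != floor(table)))
    stop("table must contain non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample is small (<= \code{exact_max_n})
#' and tie-free; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric samples
#' @param exact_max_n combined-size cutoff for the exact test
#' @return two-sided p-value
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 20) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= exact_max_n) && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Hypergeometric over-representation analysis of gene sets
#'
#' For each set, the upper-tail hypergeometric probability P(X >= overlap) of
#' drawing at least the observed overlap when sampling |gene_list| genes from
#' the universe; adjusted across sets by Benjamini-Yekutieli. Run separately
#' for up- and down-regulated lists.
#'
#' @param gene_list character vector, a subset of \code{universe}
#' @param universe character vector of all testable genes
#' @param gene_sets named list of gene symbol vectors (e.g. from
#'   \code{\link{read_gmt}})
#' @param params \code{\link{stat_params}} (uses \code{top_k_pathways})
#' @return data.frame per set: set, set_size (in universe), overlap, p, adj_p,
#'   ordered by adj_p then p; sets with empty universe intersection are skipped
#' @export
ora_enrichment <- function(gene_list, universe, gene_sets, params = stat_params()) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) stop("gene_list must be a subset of universe")
  rows <- lapply(names(gene_sets), function(nm) {
    k <- intersect(gene_sets[[nm]], universe)
    if (!length(k)) return(NULL)
    ov <- length(intersect(k, gene_list))
    p <- stats::phyper(ov - 1, length(k), length(universe) - length(k),
                       length(gene_list), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(k), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(set = character(), set_size = integer(),
                                      overlap = integer(), p = numeric(),
                                      adj_p = numeric()))
  res$adj_p <- benjamini_yekutieli(res$p)
  res[order(res$adj_p, res$p), , drop = FALSE]
}

#' Top enriched pathways by adjusted p-value
#' @param ora result of \code{\link{ora_enrichment}}
#' @param k number of pathways to keep (default the study's 10)
#' @return head of the ranked table
#' @export
top_pathways <- function(ora, k = 10L) utils::head(ora, k)

# vectorized two-sided rank-sum p-values for every column of a matrix,
# normal approximation with tie and continuity corrections (matches
# wilcox.test(exact = FALSE, correct = TRUE) per gene)
.rank_sum_p_matrix <- function(M, in_x) {
  M <- as.matrix(M)
  n1 <- sum(in_x); n2 <- sum(!in_x); n <- n1 + n2
  R <- apply(M, 2, rank)
  W <- colSums(R[in_x, , drop = FALSE]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  tie_term <- apply(M, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}
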