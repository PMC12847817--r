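# brute-force BY step-up, straight from the definition
by_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[i] <- min(1, min(m * cm * p[o][js] / js))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("Benjamini-Yekutieli matches the hand-evaluated example", {
  # m = 4, c(m) = 1 + 1/2 + 1/3 + 1/4 = 25/12; all four collapse to
  # 4 * (25/12) * 0.01 / 1 = 1/12
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.03, 0.04)),
               rep(1 / 12, 4), tolerance = 1e-12)
  expect_equal(benjamini_yekutieli(0.2), 0.2)
  expect_equal(benjamini_yekutieli(numeric(0)), numeric(0))
})

test_that("Benjamini-Yekutieli equals the brute-force step-up and dominates raw p", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- benjamini_yekutieli(p)
    expect_equal(adj, by_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("2x2 chi-squared matches hand evaluation and is symmetric", {
  r <- chi_square_2x2(matrix(c(30, 20, 20, 30), 2))
  expect_equal(r$statistic, 4, tolerance = 1e-12)  # expected 25 per cell
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1)
  t1 <- matrix(c(12, 5, 30, 44), 2)
  expect_equal(chi_square_2x2(t(t1))$statistic, chi_square_2x2(t1)$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("rank-sum test is exact for small tie-free samples and symmetric", {
  # {1,2} vs {3,4}: the most extreme of C(4,2)=6 rank splits, two-sided 2/6
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  x <- rnorm(8); y <- rnorm(6)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
})

test_that("vectorized rank-sum p-values match wilcox.test per gene", {
  set.seed(17)
  M <- matrix(rpois(600, 3), 60, 10)
  grp <- rep(c(TRUE, FALSE), each = 30)
  p_fast <- mucosaSMI:::.rank_sum_p_matrix(M, grp)
  p_ref <- apply(M, 2, function(col)
    suppressWarnings(wilcox.test(col[grp], col[!grp], exact = FALSE,
                                 correct = TRUE)$p.value))
  expect_equal(unname(p_fast), unname(p_ref), tolerance = 1e-10)
})

test_that("volcano categories follow the published thresholds", {
  p <- stat_params()
  expect_equal(volcano_classify(1.3, 0.001, 0.004, p), "dark_red")
  expect_equal(volcano_classify(1.3, 0.04, 0.30, p), "light_red")
  expect_equal(volcano_classify(0.80, 0.04, 0.30, p), "light_blue")
  expect_equal(volcano_classify(0.80, 0.001, 0.01, p), "dark_blue")
  expect_equal(volcano_classify(1.0, 1.0, 1.0, p), "ns")
  # FC inside (0.83, 1.2) is never colored regardless of p
  expect_equal(volcano_classify(1.1, 1e-6, 1e-6, p), "ns")
})

test_that("composition significance codes are gated by fold change", {
  p <- stat_params()
  expect_equal(significance_code(0.01, 1.6, p), "*")
  expect_equal(significance_code(0.0005, 0.5, p), "***")
  expect_equal(significance_code(0.01, 1.2, p), "")   # FC gate fails
  expect_equal(significance_code(0.2, 3, p), "")      # adj p gate fails
  expect_equal(significance_code(NA, 3, p), "")
})

test_that("hypergeometric ORA matches exact enumeration", {
  # universe 20, set 5, list 4, overlap 3:
  # [C(5,3)C(15,1) + C(5,4)C(15,0)] / C(20,4) = 155/4845
  sets <- list(S = paste0("g", 1:5))
  uni <- paste0("g", 1:20)
  res <- ora_enrichment(paste0("g", c(1, 2, 3, 10)), uni, sets)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  # zero overlap: P(X >= 0) = 1
  expect_equal(ora_enrichment(paste0("g", 11:14), uni, sets)$p, 1)
  expect_equal(ora_enrichment(uni, uni, list(S = uni))$p, 1)
  expect_error(ora_enrichment("notingenome", uni, sets), "subset")
  # a set disjoint from the universe is skipped
  res2 <- ora_enrichment(paste0("g", 1:2), uni,
                         list(S = paste0("g", 1:5), OFF = c("zz1", "zz2")))
  expect_equal(res2$set, "S")
})

test_that("composition test recovers a planted colonocyte enrichment", {
  sim <- tiny_cohort(seed = 21, n = c(IBD = 4L, PD = 1L, NHC = 4L),
                     cells_per_fov = 400L,
                     base_composition = c(colonocyte = 0.10, goblet = 0.22,
                                          M2_macrophage = 0.10, neutrophil = 0.08,
                                          IgA_plasma = 0.18, myofibroblast = 0.12,
                                          CD4_T = 0.12, CD8_T = 0.08),
                     composition_multipliers = list(IBD = c(colonocyte = 2)),
                     dirichlet_conc = 1000)
  truth <- sim$truth$cells
  ann <- as_annotation(truth$cell_id, truth$refined)
  res <- composition_test(ann, sim$cells, comparisons = "IBD")
  row <- res[res$cluster == "colonocyte", ]
  expect_gt(row$fc, 1.5)
  expect_true(row$code != "")
  # swapping the cell order changes nothing
  perm <- sample(nrow(ann))
  res2 <- composition_test(ann[perm, ], sim$cells, comparisons = "IBD")
  expect_equal(res2[res2$cluster == "colonocyte", "chi2"], row$chi2)
})

test_that("differential expression flips sign under reversed comparison", {
  sim <- tiny_cohort(seed = 23, n = c(IBD = 2L, PD = 2L, NHC = 2L),
                     cells_per_fov = 600L)
  pre <- annotate_cohort(sim)
  de_ibd <- differential_expression(pre$norm, pre$annotation, pre$cells,
                                    "colonocyte", "IBD")
  # planted effects: FTH1 up, SLC40A1 down in IBD colonocytes
  expect_equal(de_ibd$category[de_ibd$gene == "FTH1"], "dark_red")
  expect_equal(de_ibd$category[de_ibd$gene == "SLC40A1"], "dark_blue")
  # reversing arms by relabeling groups flips log2FC exactly
  cells_sw <- pre$cells
  cells_sw$group[cells_sw$group == "IBD"] <- "tmp"
  cells_sw$group[cells_sw$group == "NHC"] <- "IBD"
  cells_sw$group[cells_sw$group == "tmp"] <- "NHC"
  de_sw <- differential_expression(pre$norm, pre$annotation, cells_sw,
                                   "colonocyte", "IBD")
  expect_equal(de_sw$log2fc, -de_ibd$log2fc, tolerance = 1e-9)
  expect_equal(de_sw$p, de_ibd$p, tolerance = 1e-9)
  expect_error(differential_expression(pre$norm, pre$annotation, pre$cells,
                                       "colonocyte", "IBD",
                                       params = stat_params(de_min_cells = 1e6)),
               "fewer than")
})

test_that("expression density summaries integrate to one and rank types", {
  sim <- tiny_cohort(seed = 25)
  truth <- sim$truth$cells
  ann <- as_annotation(truth$cell_id, truth$refined)
  ed <- expression_density(sim$counts, ann, sim$cells, "FTH1")
  # colonocytes carry the highest mean FTH1 in every group
  for (g in unique(ed$summary$group)) {
    s <- ed$summary[ed$summary$group == g, ]
    expect_equal(s$type[which.max(s$mean_count)], "colonocyte")
  }
  # each density curve integrates to ~1 on its grid
  for (key in unique(paste(ed$density$group, ed$density$type))) {
    d <- ed$density[paste(ed$density$group, ed$density$type) == key, ]
    area <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 0.01)
  }
  expect_error(expression_density(sim$counts, ann, sim$cells, "NOSUCH"),
               "not in panel")
})

test_that("an all-zero gene yields zero means", {
  M <- matrix(0L, 4, 2, dimnames = list(paste0("c", 1:4), c("gA", "gB")))
  M[, "gB"] <- 1L
  ann <- as_annotation(paste0("c", 1:4), rep("t1", 4))
  cells <- make_cells(4, ids = paste0("c", 1:4))
  ed <- expression_density(count_matrix(M), ann, cells, "gA")
  expect_true(all(ed$summary$mean_count == 0))
})
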