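test_that("neighbor pairs follow the closed-ball, within-FOV contract", {
  cells <- make_cells(3, x = c(0, 24, 50), y = c(0, 0, 0))
  p <- neighbor_pairs(cells, 25)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$cell_i, p$cell_j), cells$cell_id[1:2])
  expect_equal(p$distance, 24)
  # distance exactly at the radius is included
  cells2 <- make_cells(2, x = c(0, 25), y = c(0, 0))
  expect_equal(nrow(neighbor_pairs(cells2, 25)), 1)
  # identical coordinates in different FOVs never pair
  cells3 <- make_cells(2, x = c(0, 0), y = c(0, 0), fov = c("f1", "f2"))
  expect_equal(nrow(neighbor_pairs(cells3, 25)), 0)
})

test_that("neighbor pairs match the brute-force oracle on random layouts", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:120, 1)
    cells <- make_cells(n, x = runif(n, 0, 150), y = runif(n, 0, 150),
                        fov = sample(c("f1", "f2"), n, replace = TRUE))
    r <- runif(1, 5, 40)
    got <- neighbor_pairs(cells, r)
    want <- neighbor_oracle(cells, r)
    if (is.null(want)) expect_equal(nrow(got), 0) else {
      expect_equal(pair_key(got), pair_key(want))
    }
  }
})

test_that("marker stratification splits only the source type on raw counts", {
  M <- matrix(0L, 3, 2, dimnames = list(paste0("c", 1:3), c("FTH1", "ACTB")))
  M[1, "FTH1"] <- 3L; M[3, "FTH1"] <- 7L
  ann <- as_annotation(paste0("c", 1:3), c("colonocyte", "colonocyte", "CD8_T"))
  s <- marker_stratify(ann, count_matrix(M), spatial_params())
  expect_equal(unname(s), c("colonocyte_FTH1+", "colonocyte_FTH1-", "CD8_T"))
  expect_error(marker_stratify(ann, count_matrix(M),
                               spatial_params(marker_gene = "GONE")),
               "not in panel")
})

test_that("LR scores are per-pair products averaged over qualifying edges", {
  cells <- make_cells(4, x = c(0, 10, 100, 110), y = rep(0, 4),
                      ids = paste0("c", 1:4))
  prs <- neighbor_pairs(cells, 25)   # (c1,c2) and (c3,c4)
  expr <- matrix(0, 4, 2, dimnames = list(paste0("c", 1:4), c("L", "R")))
  expr["c1", "L"] <- 2; expr["c2", "R"] <- 3
  expr["c3", "L"] <- 2; expr["c4", "R"] <- 3
  strata <- setNames(c("src", "tgt", "src", "tgt"), paste0("c", 1:4))
  lr <- data.frame(ligand = "L", receptor = "R")
  sc <- lr_interaction_scores(prs, expr, strata, lr, "src")
  expect_equal(sc$score[sc$target == "tgt"], 6)  # one-pair mean, duplicated pair keeps it
  expect_equal(sc$n_pairs[sc$target == "tgt"], 2)
  # ligand expressed nowhere gives score 0
  expr0 <- expr; expr0[, "L"] <- 0
  sc0 <- lr_interaction_scores(prs, expr0, strata, lr, "src")
  expect_equal(sc0$score[sc0$target == "tgt"], 0)
  # absent LR genes are skipped with a message
  expect_message(
    none <- lr_interaction_scores(prs, expr, strata,
                                  data.frame(ligand = "X", receptor = "Y"), "src"),
    "skipped")
  expect_equal(nrow(none), 0)
})

test_that("permutation p-values obey the +1 formula and determinism", {
  set.seed(77)
  n <- 60
  cells <- make_cells(n, x = runif(n, 0, 120), y = runif(n, 0, 120))
  prs <- neighbor_pairs(cells, 30)
  # strong real coupling: sources express L, targets express R
  strata <- setNames(rep(c("src", "tgt"), n / 2), cells$cell_id)
  expr <- matrix(rlnorm(2 * n, 0, 0.1), n, 2,
                 dimnames = list(cells$cell_id, c("L", "R")))
  expr[strata == "src", "L"] <- expr[strata == "src", "L"] + 5
  expr[strata == "tgt", "R"] <- expr[strata == "tgt", "R"] + 5
  lr <- data.frame(ligand = "L", receptor = "R")
  sp <- spatial_params(n_permutations = 199L, seed = 5L)
  r1 <- permutation_significance(prs, expr, strata, cells$fov, lr, "src", sp)
  # the observed coupling beats every permutation: p = 1/(N+1)
  expect_equal(r1$p[r1$target == "tgt"], 1 / 200)
  r2 <- permutation_significance(prs, expr, strata, cells$fov, lr, "src", sp)
  expect_identical(r1, r2)
  sp2 <- sp; sp2$seed <- 6L
  r3 <- permutation_significance(prs, expr, strata, cells$fov, lr, "src", sp2)
  expect_identical(r3$score, r1$score)   # observed scores ignore the seed
  expect_error(permutation_significance(prs, expr, strata, cells$fov, lr, "src",
                                        within(sp, n_permutations <- 50L)),
               "at least 100")
})

test_that("connection map classifies edges by partner marker status", {
  cells <- make_cells(4, x = c(0, 10, 20, 200), y = rep(0, 4),
                      ids = paste0("c", 1:4))
  prs <- neighbor_pairs(cells, 25)
  strata <- setNames(c("colonocyte_FTH1+", "CD8_T", "goblet", "CD4_T"),
                     cells$cell_id)
  mpos <- setNames(c(TRUE, TRUE, FALSE, FALSE), cells$cell_id)
  em <- connection_map_export(prs, strata, mpos, "f1", spatial_params())
  expect_equal(nrow(em), nrow(prs[prs$fov == "f1", ]))
  get <- function(a, b) em$class[(em$cell_i == a & em$cell_j == b) |
                                   (em$cell_i == b & em$cell_j == a)]
  expect_equal(get("c1", "c2"), "to_marker_pos")
  expect_equal(get("c1", "c3"), "to_marker_neg")
  expect_equal(get("c2", "c3"), "other")
})

test_that("planted attraction with a co-expressed LR pair is detected", {
  sim <- simulate_cohort(sim_config(
    n_patients = c(IBD = 2L, PD = 1L, NHC = 2L), cells_per_fov = 300L,
    seed = 61,
    attraction = list(target_type = "IgA_plasma", strength = 0.7,
                      range_um = 25, groups = c("IBD", "PD"))))
  pre <- annotate_cohort(sim)
  ia <- interaction_analysis(pre$counts, pre$norm, pre$annotation, pre$cells,
                             data.frame(ligand = "CCL20", receptor = "CCR6"),
                             spatial_params(n_permutations = 199L, seed = 9L))
  cnt <- ia$counts
  pick <- function(g, s) cnt$n_significant[cnt$group == g & cnt$stratum ==
                                             paste0("colonocyte_FTH1", s)]
  expect_gt(pick("IBD", "+"), pick("IBD", "-"))
  expect_gt(pick("IBD", "+"), pick("NHC", "+"))
  # the planted plasma-target row itself is significant in IBD
  res <- ia$results
  row <- res[res$group == "IBD" & res$stratum == "colonocyte_FTH1+" &
               res$target == "IgA_plasma", ]
  expect_true(any(row$significant))
})
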