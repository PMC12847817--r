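test_that("simulation is deterministic given seed", {
  a <- tiny_cohort(seed = 3, n = c(IBD = 1L, PD = 1L, NHC = 1L), cells_per_fov = 80L)
  b <- tiny_cohort(seed = 3, n = c(IBD = 1L, PD = 1L, NHC = 1L), cells_per_fov = 80L)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$protein$counts, b$protein$counts)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- tiny_cohort(seed = 4, n = c(IBD = 1L, PD = 1L, NHC = 1L), cells_per_fov = 80L)
  expect_false(identical(as.matrix(a$counts$counts), as.matrix(c$counts$counts)))
})

test_that("every cell appears exactly once in the truth", {
  sim <- tiny_cohort(seed = 5, cells_per_fov = 100L)
  expect_setequal(sim$truth$cells$cell_id, cell_ids(sim$counts))
  expect_equal(anyDuplicated(sim$truth$cells$cell_id), 0)
  expect_identical(sim$cells$cell_id, cell_ids(sim$counts))
  expect_identical(sim$cells$cell_id, cell_ids(sim$protein))
})

test_that("NB counts are over-dispersed when dispersion is positive", {
  sim <- simulate_cohort(sim_config(
    n_patients = c(IBD = 1L, PD = 1L, NHC = 1L), cells_per_fov = 2000L,
    fovs_per_patient = 1L, nb_dispersion = 0.5, seed = 6))
  truth <- sim$truth$cells
  g <- gene_counts(sim$counts)
  # within one (type, group) stratum and a high-mean gene, var > mean
  sel <- truth$refined == "goblet" & truth$group == "NHC"
  x <- as.numeric(g[sel, "MUC2"])
  expect_gt(length(x), 300)
  expect_gt(var(x), mean(x) * 1.3)
})

test_that("planted DE fold change is recovered in the raw means", {
  sim <- simulate_cohort(sim_config(
    n_patients = c(IBD = 3L, PD = 1L, NHC = 4L), cells_per_fov = 1500L,
    fovs_per_patient = 2L, seed = 7,
    de_effects = list(IBD = list(colonocyte = c(FTH1 = 2)))))
  truth <- sim$truth$cells
  g <- gene_counts(sim$counts)
  col_ibd <- truth$refined == "colonocyte" & truth$group == "IBD"
  col_nhc <- truth$refined == "colonocyte" & truth$group == "NHC"
  expect_gt(sum(col_ibd), 2000)
  expect_gt(sum(col_nhc), 2000)
  ratio <- mean(g[col_ibd, "FTH1"]) / mean(g[col_nhc, "FTH1"])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("null multipliers leave per-group compositions equal within MC error", {
  # replicate-simulation oracle: 20 null replicates estimate the Monte-Carlo
  # SE of per-group mean colonocyte share; group differences stay within 3 SE
  shares <- t(vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(
      n_patients = c(IBD = 2L, PD = 2L, NHC = 2L), cells_per_fov = 150L,
      fovs_per_patient = 1L, composition_multipliers = list(), seed = 100 + s))
    tr <- sim$truth$cells
    vapply(c("IBD", "PD", "NHC"), function(g)
      mean(tr$refined[tr$group == g] == "colonocyte"), 0)
  }, numeric(3)))
  se <- apply(shares, 2, sd) / sqrt(nrow(shares))
  mns <- colMeans(shares)
  expect_lt(max(mns) - min(mns), 3 * max(se))
})

test_that("area outliers are planted and recoverable", {
  sim <- tiny_cohort(seed = 8, cells_per_fov = 150L,
                     planted_outlier_fraction = 0.01)
  out <- sim$truth$planted_area_outliers
  expect_gt(length(out), 0)
  med <- median(sim$cells$area[!sim$cells$cell_id %in% out])
  expect_true(all(sim$cells$area[sim$cells$cell_id %in% out] > 2 * med))
})

test_that("attraction off matches complete spatial randomness pair counts", {
  # with no attraction, FTH1+ colonocyte / plasma pair counts inside 25 um
  # match the CSR expectation n_pos * n_tgt * pi r^2 / A within 3 SE over
  # replicates (edge effects make the observation slightly conservative)
  obs <- exp_ <- numeric(12)
  for (s in seq_along(obs)) {
    sim <- simulate_cohort(sim_config(
      n_patients = c(IBD = 1L, PD = 1L, NHC = 1L), fovs_per_patient = 1L,
      cells_per_fov = 400L, seed = 200 + s))
    tr <- sim$truth$cells
    prs <- neighbor_pairs(sim$cells, 25)
    lab <- setNames(ifelse(tr$refined == "colonocyte" & tr$marker_pos, "pos",
                    ifelse(tr$refined == "IgA_plasma", "tgt", "other")),
                    tr$cell_id)
    li <- lab[prs$cell_i]; lj <- lab[prs$cell_j]
    obs[s] <- sum((li == "pos" & lj == "tgt") | (li == "tgt" & lj == "pos"))
    per_fov <- table(tr$fov, lab)
    exp_[s] <- sum(per_fov[, "pos"] * per_fov[, "tgt"] * pi * 25^2 / 500^2)
  }
  se <- sd(obs - exp_) / sqrt(length(obs))
  expect_lt(abs(mean(obs - exp_)), 3 * max(se, 1))
})

test_that("attraction enriches within-radius pairs and marker truth is recorded", {
  cfgs <- list(off = 0, on = 0.8)
  cnt <- vapply(names(cfgs), function(k) {
    sim <- simulate_cohort(sim_config(
      n_patients = c(IBD = 2L, PD = 1L, NHC = 1L), fovs_per_patient = 1L,
      cells_per_fov = 400L, seed = 33,
      attraction = list(target_type = "IgA_plasma", strength = cfgs[[k]],
                        range_um = 25, groups = "IBD")))
    tr <- sim$truth$cells
    ibd <- sim$cells[sim$cells$group == "IBD", ]
    prs <- neighbor_pairs(ibd, 25)
    pos <- tr$cell_id[tr$refined == "colonocyte" & tr$marker_pos]
    tgt <- tr$cell_id[tr$refined == "IgA_plasma"]
    sum((prs$cell_i %in% pos & prs$cell_j %in% tgt) |
          (prs$cell_j %in% pos & prs$cell_i %in% tgt))
  }, 0)
  expect_gt(cnt["on"], 2 * cnt["off"])
})

test_that("fluid panel recovers the planted log-scale correlation", {
  cfg0 <- sim_config(seed = 41, fluid = list(
    n = c(IBD = 10000L, PD = 3L, NHC = 3L),
    analytes = c("CCL22", "ferritin"),
    meanlog = c(CCL22 = log(400), ferritin = log(50)),
    group_shift = list(), sdlog = 0.5,
    rho = c(IBD = 0, PD = 0, NHC = 0),
    duration_range = c(2, 15), duration_r2 = 0))
  p0 <- simulate_fluid_panel(cfg0)$panel
  r0 <- cor(log(p0$CCL22[p0$group == "IBD"]), log(p0$ferritin[p0$group == "IBD"]))
  expect_lt(abs(r0), 0.03)
  cfg1 <- cfg0
  cfg1$fluid$n <- c(IBD = 1000L, PD = 3L, NHC = 3L)
  cfg1$fluid$rho <- c(IBD = 0.75, PD = 0, NHC = 0)
  p1 <- simulate_fluid_panel(cfg1)$panel
  r1 <- cor(log(p1$CCL22[p1$group == "IBD"]), log(p1$ferritin[p1$group == "IBD"]))
  expect_gt(r1, 0.70); expect_lt(r1, 0.80)
  # determinism
  p2 <- simulate_fluid_panel(cfg1)$panel
  expect_identical(p1, p2)
  cfg_bad <- cfg1
  expect_error(sim_config(seed = 1, fluid = within(cfg1$fluid, rho <- c(IBD = 1))),
               "rho")
})
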