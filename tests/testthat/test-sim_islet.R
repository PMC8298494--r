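test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_sc(cfg)
  b <- simulate_sc(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth$cells, b$truth$cells)
  bk1 <- simulate_bulk(cfg)
  bk2 <- simulate_bulk(cfg)
  expect_identical(as.matrix(bk1$counts$counts), as.matrix(bk2$counts$counts))
})

test_that("zero bihormonal proportions yield no two-hormone cells", {
  cfg <- small_sim_config(seed = 2,
                          bihorm_proportions = c(gamma_alpha = 0,
                                                 gamma_delta = 0,
                                                 gamma_beta = 0))
  sim <- simulate_sc(cfg)
  expect_false(any(grepl("+", sim$truth$cells$hormones, fixed = TRUE)))
})

test_that("gamma-lineage cell count follows the configured binomial", {
  cfg <- sim_config(n_cells = 5000, seed = 11)
  sim <- simulate_sc(cfg)
  n_gamma <- sum(startsWith(sim$truth$cells$population, "gamma"))
  expect_lt(abs(n_gamma - 500), 3 * sqrt(5000 * 0.1 * 0.9))
  # the sorted-fraction flag marks exactly the gamma lineage
  expect_identical(sim$counts$cell_meta$fraction == "positive",
                   startsWith(sim$truth$cells$population, "gamma"))
})

test_that("configs that starve a subpopulation or break bimodality are rejected", {
  expect_error(simulate_sc(sim_config(n_cells = 500)), "fewer than 10")
  expect_error(sim_config(hormone_high_mean = 1, hormone_low_mean = 2),
               "must exceed")
  expect_error(sim_config(hormone_high_mean = 1.1, hormone_low_mean = 1,
                          hormone_sd = 0.5), "2 \\* hormone_sd")
  expect_error(sim_config(type_proportions = c(alpha = 0.5, beta = 0.5,
                                               delta = 0.2, gamma = 0.1)),
               "sum to 1")
})

test_that("bulk simulation has the requested shape and truth marks null genes", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_bulk(cfg, n_samples_per_type = 3)
  expect_equal(ncol(sim$counts$counts), 12)
  tg <- sim$truth$genes
  bg <- tg[tg$role == "background", ]
  expect_true(all(bg$true_log2fc_gamma_vs_alpha == 0))
  idg <- tg[tg$role == "id_gamma", ]
  expect_true(all(idg$true_log2fc_gamma_vs_alpha >= 1))
  expect_true(all(idg$true_log2fc_gamma_vs_beta >= 1))
  expect_true(all(idg$true_log2fc_gamma_vs_delta >= 1))
})

test_that("bulk counts match negative binomial moments", {
  # many samples of one type: empirical variance ~ m + d * m^2
  set.seed(99)
  m_true <- 50; d_true <- 0.1
  draws <- stats::rnbinom(600, size = 1 / d_true, mu = m_true)
  # oracle moment relation on a directly drawn control
  expect_lt(abs(stats::var(draws) / (m_true + d_true * m_true^2) - 1), 0.35)
  # the generator's own draws obey the same relation gene by gene
  cfg <- small_sim_config(seed = 12, libsize_sigma = 0)
  sim <- simulate_bulk(cfg, n_samples_per_type = 250, depth = 1,
                       dispersion = 0.2)
  counts <- as.matrix(sim$counts$counts)
  alpha_cols <- sim$truth$samples$cell_type == "alpha"
  sub <- counts[sim$truth$genes$role == "background", alpha_cols]
  mean_g <- rowMeans(sub)
  var_g <- apply(sub, 1, stats::var)
  keep <- mean_g > 5
  ratio <- var_g[keep] / (mean_g[keep] + 0.2 * mean_g[keep]^2)
  expect_lt(abs(stats::median(ratio) - 1), 0.15)
})

test_that("realized type proportions converge to the configured mixture", {
  cfg <- sim_config(n_cells = 20000, n_genes = 150, n_id_genes_per_type = 5,
                    seed = 21)
  sim <- simulate_sc(cfg)
  freq <- table(sim$truth$cells$base_type) / 20000
  target <- c(alpha = 0.35, beta = 0.45, delta = 0.10, gamma = 0.10)
  expect_true(all(abs(freq[names(target)] - target) < 0.01))
})

test_that("hormone genes are bimodal with positive amplitude in the default generator", {
  sim <- simulate_sc(small_sim_config(seed = 5))
  nm <- log_normalize(qc_filter(sim$counts))
  thr <- hormone_thresholds(nm, unname(sim$truth$hormones))
  for (h in names(thr)) expect_gt(thr[[h]]$amplitude, 0)
})

test_that("planted low-quality cells are flagged in truth and depleted in depth", {
  cfg <- small_sim_config(seed = 9, lowq_cell_frac = 0.02)
  sim <- simulate_sc(cfg)
  expect_equal(sum(sim$truth$cells$lowq), round(0.02 * 2500))
  totals <- Matrix::colSums(sim$counts$counts)
  expect_true(all(totals[sim$truth$cells$lowq] < 1000))
})

test_that("simulation round-trips through the MTX triplet on disk", {
  sim <- simulate_sc(small_sim_config(seed = 4))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_counts(file.path(dir, "matrix.mtx"),
                      file.path(dir, "features.tsv"),
                      file.path(dir, "barcodes.tsv"),
                      cell_meta_path = file.path(dir, "cell_meta.tsv"))
  expect_identical(as.matrix(back$counts), as.matrix(sim$counts$counts))
  expect_identical(back$cell_meta$cluster, sim$counts$cell_meta$cluster)
})

test_that("a YAML config round-trips into a validated sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cells: 3000", "seed: 5", "type_proportions:",
               "  alpha: 0.3", "  beta: 0.5", "  delta: 0.1", "  gamma: 0.1"),
             path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_cells, 3000)
  expect_equal(cfg$type_proportions[["beta"]], 0.5)
  writeLines("bogus_field: 1", path)
  expect_error(read_sim_config(path), "unknown config fields")
})
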