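test_that("density estimation recovers a known bimodal mixture", {
  set.seed(31)
  v <- c(stats::rnorm(5000, 0.1, 0.05), stats::rnorm(5000, 3.0, 0.3))
  v <- v[v >= 0]
  curve <- estimate_density(v)
  th <- find_antimode(curve)
  expect_equal(nrow(th$modes), 2)
  expect_lt(abs(th$modes$location[1] - 0.1), 0.1)
  expect_lt(abs(th$modes$location[2] - 3.0), 0.2)
  # trapezoidal integral is 1
  integral <- sum(diff(curve$grid) *
                    (utils::head(curve$density, -1) + utils::tail(curve$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.01)
  # grid covers [0, max] and is strictly increasing
  expect_lte(curve$grid[1], 0)
  expect_gte(curve$grid[length(curve$grid)], max(v))
  expect_true(all(diff(curve$grid) > 0))
})

test_that("degenerate or scant inputs are rejected", {
  expect_error(estimate_density(rep(1, 500)), "identical")
  expect_error(estimate_density(stats::rnorm(50)), "at least 100")
})

test_that("a symmetric equal mixture thresholds at the midpoint", {
  set.seed(32)
  v <- c(stats::rnorm(5000, -1, 0.25), stats::rnorm(5000, 1, 0.25))
  th <- find_antimode(estimate_density(v))
  expect_lt(abs(th$threshold), 0.1)
  expect_gt(th$amplitude, 0)
})

test_that("antimode equals the exhaustive interior-minimum oracle", {
  set.seed(33)
  cases <- list(
    c(stats::rnorm(4000, 0.1, 0.05), stats::rnorm(4000, 3, 0.3)),
    c(stats::rnorm(6000, 0, 0.5), stats::rnorm(2000, 4, 0.8)),
    c(stats::rnorm(1000, 1, 0.2), stats::rnorm(5000, 5, 1.0)),
    c(stats::rexp(3000, 2), stats::rnorm(3000, 6, 0.5)))
  for (v in cases) {
    curve <- estimate_density(v)
    th <- find_antimode(curve)
    expect_equal(th$threshold, oracle_antimode(curve))
    # antimode lies strictly between the principal modes, below both peaks
    expect_gt(th$threshold, th$modes$location[1])
    expect_lt(th$threshold, th$modes$location[2])
    expect_lte(th$antimode_height, min(th$modes$height))
  }
})

test_that("a strictly unimodal sample raises the unimodal error", {
  set.seed(34)
  v <- stats::rnorm(10000, 2, 0.5)
  curve <- estimate_density(v)
  expect_null(oracle_antimode(curve))
  expect_error(find_antimode(curve), "unimodal")
})

test_that("weak bimodality is flagged low-confidence", {
  set.seed(35)
  # heavily overlapping components: shallow valley
  v <- c(stats::rnorm(20000, 0, 1), stats::rnorm(20000, 2.6, 1))
  curve <- estimate_density(v, bandwidth = 0.45)
  expect_warning(th <- find_antimode(curve, amplitude_floor = 0.5),
                 "low-confidence")
  expect_true(th$low_confidence)
})

test_that("threshold shifts with an additive constant (scale consistency)", {
  set.seed(36)
  v <- c(stats::rnorm(4000, 0.2, 0.1), stats::rnorm(4000, 3, 0.4))
  t0 <- find_antimode(estimate_density(v))$threshold
  t5 <- find_antimode(estimate_density(v + 5))$threshold
  expect_lt(abs((t5 - t0) - 5), 0.05)
})

test_that("hormone status uses a strict inequality at the threshold", {
  vals <- matrix(c(0.5, 0.5000001, 0.4999999, 0), nrow = 1,
                 dimnames = list("Ppy", paste0("c", 1:4)))
  nm <- structure(list(values = methods::as(vals, "CsparseMatrix"),
                       scale_factor = 1e4, totals = rep(1, 4)),
                  class = "islet_norm")
  st <- assign_hormone_status(nm, c(Ppy = 0.5))
  expect_identical(as.vector(st), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("all-zero cells express nothing and missing hormones error", {
  sim <- simulate_sc(small_sim_config(seed = 37))
  nm <- log_normalize(qc_filter(sim$counts))
  thr <- hormone_thresholds(nm, unname(sim$truth$hormones))
  expect_true(all(vapply(thr, function(t) t$threshold, 0) > 0))
  expect_error(hormone_thresholds(nm, c("Gcg", "NotAGene")), "NotAGene")
})

test_that("identity labels are injective over all hormone subsets", {
  hs <- c("Gcg", "Ins2", "Ppy", "Sst")
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  status <- t(as.matrix(subsets))
  rownames(status) <- hs
  colnames(status) <- paste0("c", seq_len(16))
  ids <- assign_identity(status)
  expect_equal(length(unique(ids$identity)), 16)
  expect_identical(ids$identity[1], "none")
  expect_false(ids$endocrine[1])
  # canonical ordering is alphabetical; anchored view lists the anchor first
  ppy_gcg <- status[, 1, drop = FALSE]; ppy_gcg[] <- FALSE
  ppy_gcg[c("Ppy", "Gcg"), 1] <- TRUE
  lab <- assign_identity(ppy_gcg)$identity
  expect_identical(lab, "Gcg+Ppy")
  expect_identical(anchored_label(lab, "Ppy"), "Ppy+Gcg")
})

test_that("cluster consistency keeps matching cells and records reasons", {
  ids <- data.frame(
    barcode = paste0("c", 1:6),
    identity = c("Gcg", "Gcg", "Gcg+Ppy", "Gcg+Ppy", "none", "Gcg+Sst"),
    n_hormones = c(1, 1, 2, 2, 0, 2),
    endocrine = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    cluster = c("alpha", "beta", "bihorm5", "alpha", "alpha", "bihorm5"),
    retained = TRUE, exclude_reason = "", stringsAsFactors = FALSE)
  class(ids) <- c("cell_identity", "data.frame")
  cmap <- c(alpha = "Gcg", beta = "Ins2", bihorm5 = "bihormonal")
  out <- cluster_consistency_filter(ids, cmap)
  expect_identical(out$retained, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$exclude_reason[2], "cluster_mismatch")
  expect_identical(out$exclude_reason[4], "bihormonal_outside_cluster")
  expect_identical(out$exclude_reason[5], "non_endocrine")
  expect_identical(out$exclude_reason[6], "multihormonal_non_anchor")
  expect_error(cluster_consistency_filter(ids, cmap[-1]), "unmapped")
})

test_that("mislabel-driven exclusions match the configured rate", {
  cfg <- small_sim_config(seed = 38)
  sim <- simulate_sc(cfg)
  kept <- qc_filter(sim$counts)
  nm <- log_normalize(kept)
  thr <- hormone_thresholds(nm, unname(sim$truth$hormones))
  ids <- assign_identity(assign_hormone_status(nm, thr), kept$cell_meta)
  ids <- cluster_consistency_filter(ids, default_cluster_map())
  n <- nrow(ids)
  excluded <- sum(!ids$retained)
  expect_lt(abs(excluded - 0.02 * n), 3 * sqrt(n * 0.02 * 0.98))
  # recovered bihormonal shares of the gamma pool track the configured split
  truth <- sim$truth$cells[match(ids$barcode, sim$truth$cells$barcode), ]
  pool <- ids$retained & grepl("Ppy", ids$identity, fixed = TRUE)
  shares <- prop.table(table(factor(truth$population[pool],
                                    levels = c("gamma", "gamma_alpha",
                                               "gamma_delta", "gamma_beta"))))
  conf <- c(1 - 0.33, 0.24, 0.05, 0.04)
  npool <- sum(pool)
  for (i in seq_along(conf))
    expect_lt(abs(shares[i] - conf[i]), 3 * sqrt(conf[i] * (1 - conf[i]) / npool))
})
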