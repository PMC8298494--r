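test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(c(10, 20, 40, 80, 100,
                10, 20, 40, 80, 100), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_true(all(sf > 0))
  # no gene expressed everywhere is an error
  m3 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(m3), "no gene expressed")
})

test_that("size factors are recovered within 2% on simulated bulk", {
  sim <- simulate_bulk(small_sim_config(seed = 61, n_genes = 2000,
                                        n_id_genes_per_type = 25))
  types <- sim$truth$samples$cell_type
  cols <- sim$truth$samples$sample[types %in% c("gamma", "alpha")]
  sf <- size_factors(sim$counts$counts[, cols])
  sf_true <- sim$truth$samples$size_factor[
    match(cols, sim$truth$samples$sample)]
  gm <- function(x) exp(mean(log(x)))
  expect_lt(max(abs(sf / gm(sf) - sf_true / gm(sf_true)) / (sf_true / gm(sf_true))),
            0.02)
  # fixed point: rescaling by the factors drives new factors to ~1
  scaled <- round(sweep(as.matrix(sim$counts$counts[, cols]), 2, sf, "/"))
  sf2 <- size_factors(scaled)
  expect_true(all(abs(sf2 - 1) < 0.01 + 0.01))
})

test_that("the mean-count filter keeps the inclusive boundary", {
  m <- matrix(c(5, 5, 5, 4, 4, 4, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("at5", "below", "zero"), paste0("s", 1:3)))
  expect_identical(mean_count_filter(m), "at5")
})

test_that("duplicated samples give zero fold changes", {
  sim <- simulate_bulk(small_sim_config(seed = 62))
  cols <- sim$truth$samples$sample[sim$truth$samples$cell_type == "alpha"]
  m <- sim$counts$counts[, c(cols, cols)]
  colnames(m) <- paste0("s", 1:6)
  res <- bulk_nb_wald(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(abs(res$lfc_mle) < 1e-6))
})

test_that("planted fold changes are recovered and calls match truth at strong effect", {
  errs <- c()
  for (seed in 1:8) {
    cfg <- small_sim_config(seed = 70 + seed, n_genes = 400,
                            n_id_genes_per_type = 5,
                            id_logfc = 2 * log(2)) # true log2FC = 2
    sim <- simulate_bulk(cfg, n_samples_per_type = 3, dispersion = 0.05)
    s <- sim$truth$samples
    res <- bulk_de_pairwise(sim$counts,
                            s$sample[s$cell_type == "gamma"],
                            s$sample[s$cell_type == "alpha"])
    idg <- intersect(sim$truth$genes$gene[sim$truth$genes$role == "id_gamma"],
                     res$gene)
    errs <- c(errs, res$lfc_mle[match(idg, res$gene)] - 2)
  }
  expect_lt(abs(stats::median(errs)), 0.3)

  # strong effect / low dispersion: the call set equals the planted DE genes
  cfg <- small_sim_config(seed = 63, n_genes = 400, n_id_genes_per_type = 5,
                          id_logfc = 2.5 * log(2))
  sim <- simulate_bulk(cfg, n_samples_per_type = 4, dispersion = 0.01)
  s <- sim$truth$samples
  res <- bulk_de_pairwise(sim$counts,
                          s$sample[s$cell_type == "gamma"],
                          s$sample[s$cell_type == "alpha"])
  tg <- sim$truth$genes
  planted <- intersect(tg$gene[abs(tg$true_log2fc_gamma_vs_alpha) >= 1],
                       res$gene)
  expect_setequal(res$gene[res$called], planted)
})

test_that("normal-prior shrinkage has the stated limits and never flips sign", {
  res <- structure(data.frame(
    gene = c("tight", "half", "noisy"),
    base_mean = c(100, 10, 2),
    lfc_mle = c(2, 2, -3), se = c(1e-9, 1, 4),
    p = c(1e-9, 0.01, 0.4), padj = c(1e-8, 0.02, 0.5),
    dispersion = 0.1, converged = TRUE),
    class = c("bulk_de_result", "data.frame"))
  sh <- shrink_lfc_normal(res, bulk_de_config(shrink_prior_sd = 1))
  expect_equal(sh$lfc_shrunk[1], 2, tolerance = 1e-6)   # se -> 0 limit
  expect_equal(sh$lfc_shrunk[2], 1, tolerance = 1e-12)  # prior_sd = se: MLE/2
  expect_true(all(abs(sh$lfc_shrunk) <= abs(sh$lfc_mle) + 1e-6))
  expect_true(all(sign(sh$lfc_shrunk) == sign(sh$lfc_mle)))
})

test_that("shrinkage helps low-count genes on average", {
  # genes with small base mean: posterior-mode estimates sit closer to truth
  set.seed(64)
  n <- 400
  true_lfc <- stats::rnorm(n, 0, 0.8)
  se <- stats::runif(n, 0.5, 1.5)          # noisy, low-count-like SEs
  mle <- true_lfc + stats::rnorm(n, 0, se)
  res <- structure(data.frame(gene = paste0("g", 1:n), base_mean = 10,
                              lfc_mle = mle, se = se, p = 0.5, padj = 0.5,
                              dispersion = 0.1, converged = TRUE),
                   class = c("bulk_de_result", "data.frame"))
  sh <- shrink_lfc_normal(res, bulk_de_config(shrink_prior_sd = 0.8))
  expect_lte(mean(abs(sh$lfc_shrunk - true_lfc)), mean(abs(mle - true_lfc)))
})

test_that("DE calls use inclusive boundaries on both criteria", {
  res <- structure(data.frame(
    gene = c("on_boundary", "strong_ns", "clear"),
    base_mean = 50, lfc_mle = c(1.2, 3.2, 2.5), se = 0.1,
    p = c(0.01, 0.15, 1e-8), padj = c(0.05, 0.2, 1e-6),
    dispersion = 0.1, converged = TRUE),
    class = c("bulk_de_result", "data.frame"))
  res$lfc_shrunk <- c(1.0, 3.0, 2.4)
  called <- call_de(res)
  expect_true("on_boundary" %in% called)   # |lfc| = 1, padj = 0.05
  expect_false("strong_ns" %in% called)
  expect_true("clear" %in% called)
})

test_that("BH-adjusted p-values are monotone and the null FDR is controlled", {
  hits <- 0; tested <- 0
  for (seed in 1:5) {
    set.seed(80 + seed)
    mu <- stats::rlnorm(400, 4, 1)
    m <- matrix(stats::rnbinom(400 * 6, size = 1 / 0.05, mu = rep(mu, 6)),
                nrow = 400, dimnames = list(paste0("g", 1:400), paste0("s", 1:6)))
    res <- bulk_nb_wald(m, paste0("s", 1:3), paste0("s", 4:6))
    ok <- !is.na(res$p)
    expect_true(all(diff(res$padj[ok][order(res$p[ok])]) >= -1e-12))
    hits <- hits + sum(res$padj[ok] <= 0.05)
    tested <- tested + sum(ok)
  }
  expect_lte(hits / tested, 0.07)
})

test_that("fold-change estimates agree with an established reference on a small dataset", {
  library(DESeq2)
  sim <- simulate_bulk(small_sim_config(seed = 65, n_genes = 300,
                                        n_id_genes_per_type = 5),
                       n_samples_per_type = 3, dispersion = 0.05)
  s <- sim$truth$samples
  cols <- s$sample[s$cell_type %in% c("gamma", "alpha")]
  cnt <- as.matrix(sim$counts$counts[, cols])
  cond <- factor(ifelse(startsWith(cols, "gamma"), "A", "B"),
                 levels = c("B", "A"))
  dds <- DESeqDataSetFromMatrix(cnt, S4Vectors::DataFrame(cond = cond), ~cond)
  dds <- DESeq(dds, quiet = TRUE)
  ref <- results(dds, name = "cond_A_vs_B")
  mine <- bulk_nb_wald(sim$counts,
                       s$sample[s$cell_type == "gamma"],
                       s$sample[s$cell_type == "alpha"])
  shared <- intersect(mine$gene, rownames(ref))
  shared <- shared[mine$converged[match(shared, mine$gene)] &
                     !is.na(ref[shared, "log2FoldChange"])]
  lfc_ref <- ref[shared, "log2FoldChange"]
  lfc_mine <- mine$lfc_mle[match(shared, mine$gene)]
  # same direction for every clearly non-null gene, tight numeric agreement
  big <- abs(lfc_ref) > 0.5
  expect_true(all(sign(lfc_mine[big]) == sign(lfc_ref[big])))
  expect_lt(stats::median(abs(lfc_mine - lfc_ref)), 0.1)
  # size factors match the reference implementation
  sf_ref <- sizeFactors(dds)
  sf_mine <- attr(mine, "size_factors")[names(sf_ref)]
  expect_equal(unname(sf_mine), unname(sf_ref), tolerance = 0.01)
})
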