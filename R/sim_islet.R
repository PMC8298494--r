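#' Configuration for the synthetic islet generator
#'
#' Defines the statistical structure of a simulated adult islet: four
#' monohormonal endocrine types (alpha, beta, delta, gamma), three bihormonal
#' gamma subtypes (gamma-alpha, gamma-delta, gamma-beta) carved out of the
#' gamma pool, hormone genes with bimodal (near-zero vs high) expression,
#' per-cell log-normal library sizes, per-gene negative binomial noise, two
#' replicates with a gene-wise batch effect, and optional doublets.
#'
#' Defaults mirror a realistic adult islet: composition alpha 0.35, beta 0.45,
#' delta 0.10, gamma 0.10; bihormonal shares 0.24 / 0.05 / 0.04 of the gamma
#' pool (gamma-alpha / gamma-delta / gamma-beta); hormone transcripts are
#' orders of magnitude above background in expressing cells.
#'
#' @param n_cells Number of cells to simulate.
#' @param type_proportions Named fractions over \code{c("alpha", "beta",
#'   "delta", "gamma")}; must sum to 1.
#' @param bihorm_proportions Named fractions of the gamma pool assigned to the
#'   bihormonal subtypes \code{c("gamma_alpha", "gamma_delta", "gamma_beta")};
#'   the remainder stays monohormonal gamma.
#' @param n_genes Total genes, including the 4 hormone genes, planted identity
#'   genes and a small mitochondrial block.
#' @param n_id_genes_per_type Planted identity genes per cell type.
#' @param id_logfc True natural-log fold change of a planted identity gene in
#'   its own type versus every other type.
#' @param id_mix_frac Fraction of the partner type's identity genes a
#'   bihormonal cell draws from the partner profile.
#' @param hormone_high_mean,hormone_low_mean Natural-log mean expression of a
#'   hormone gene in expressing / non-expressing cells (before library-size
#'   scaling). \code{hormone_high_mean} must exceed \code{hormone_low_mean}.
#' @param hormone_sd Log-scale spread of per-cell hormone means within a
#'   component.
#' @param hormone_dropout Probability that a non-expressing cell yields an
#'   exact zero for a hormone gene (zero inflation of the low component).
#' @param libsize_mu,libsize_sigma Log-normal parameters of the per-cell
#'   library-size factor (mean 0 on the log scale leaves depth centred on the
#'   gene means).
#' @param nb_dispersion Negative binomial dispersion; a scalar, or a length-2
#'   range from which gene-wise dispersions are drawn uniformly.
#' @param batch_effect_sd SD of the gene-wise multiplicative log-scale batch
#'   offset between replicates.
#' @param n_replicates Number of replicates; cells are split evenly.
#' @param mito_fraction_mean Mean fraction of a cell's counts carried by the
#'   mitochondrial gene block.
#' @param doublet_rate Fraction of cells replaced by the sum of two random
#'   singlet profiles (flagged in truth).
#' @param cluster_mislabel_rate Probability that a cell's truth-derived
#'   cluster label is perturbed to a random other cluster.
#' @param lowq_cell_frac Fraction of cells planted with a tiny library size
#'   (below usual QC depth), for exercising quality filters.
#' @param seed Integer seed; together with the config it fully determines the
#'   output.
#' @return A \code{sim_config} list, validated.
#' @export
sim_config <- function(n_cells = 5000,
                       type_proportions = c(alpha = 0.35, beta = 0.45,
                                            delta = 0.10, gamma = 0.10),
                       bihorm_proportions = c(gamma_alpha = 0.24,
                                              gamma_delta = 0.05,
                                              gamma_beta = 0.04),
                       n_genes = 2000,
                       n_id_genes_per_type = 25,
                       id_logfc = 1.2,
                       id_mix_frac = 0.5,
                       hormone_high_mean = log(800),
                       hormone_low_mean = log(0.1),
                       hormone_sd = 0.5,
                       hormone_dropout = 0.6,
                       libsize_mu = 0,
                       libsize_sigma = 0.3,
                       nb_dispersion = 0.3,
                       batch_effect_sd = 0.1,
                       n_replicates = 2,
                       mito_fraction_mean = 0.03,
                       doublet_rate = 0,
                       cluster_mislabel_rate = 0.02,
                       lowq_cell_frac = 0,
                       seed = 1L) {
  stopifnot(length(type_proportions) == 4,
            setequal(names(type_proportions),
                     c("alpha", "beta", "delta", "gamma")),
            length(bihorm_proportions) == 3,
            setequal(names(bihorm_proportions),
                     c("gamma_alpha", "gamma_delta", "gamma_beta")))
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1")
  fr <- c(type_proportions, bihorm_proportions, doublet_rate,
          cluster_mislabel_rate, hormone_dropout, mito_fraction_mean,
          id_mix_frac, lowq_cell_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (sum(bihorm_proportions) > 1)
    stop("bihorm_proportions exceed the gamma pool")
  if (hormone_high_mean <= hormone_low_mean)
    stop("hormone_high_mean must exceed hormone_low_mean (bimodality)")
  if (hormone_high_mean - hormone_low_mean < 2 * hormone_sd)
    stop("hormone component means must differ by at least 2 * hormone_sd")
  stopifnot(n_cells >= 1, n_genes > 4 * (1 + n_id_genes_per_type),
            n_replicates >= 1, id_logfc > 0, nb_dispersion > 0)
  cfg <- mget(names(formals(sim_config)))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Read a simulator configuration from a YAML file
#'
#' Scalar fields override \code{\link{sim_config}} defaults; named maps
#' (\code{type_proportions}, \code{bihorm_proportions}) are given as YAML
#' mappings.
#'
#' @param path YAML file path.
#' @return A validated \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  for (f in c("type_proportions", "bihorm_proportions"))
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  do.call(sim_config, y)
}

# Gene panel layout shared by the single-cell and bulk generators.
# Hormone genes carry the field's mouse names; identity genes and background
# are synthetic. Returns per-gene metadata plus per-type log-mean profiles.
sim_gene_panel <- function(cfg) {
  types <- c("alpha", "beta", "delta", "gamma")
  hormones <- c(alpha = "Gcg", beta = "Ins2", delta = "Sst", gamma = "Ppy")
  n_mito <- 5
  n_id <- cfg$n_id_genes_per_type * 4
  n_bg <- cfg$n_genes - 4 - n_id - n_mito
  stopifnot(n_bg > 0)
  id_names <- unlist(lapply(types, function(t)
    sprintf("ID.%s.%02d", t, seq_len(cfg$n_id_genes_per_type))))
  gene_names <- c(unname(hormones), id_names,
                  sprintf("mt-Sim%d", seq_len(n_mito)),
                  sprintf("Bg%04d", seq_len(n_bg)))
  role <- c(rep("hormone", 4),
            rep(paste0("id_", types), each = cfg$n_id_genes_per_type),
            rep("mito", n_mito), rep("background", n_bg))
  # background log-means spread over a realistic dynamic range; planted
  # identity genes sit in the moderate-to-high band markers occupy, so their
  # fold changes survive the pseudocount in the downstream lnFC formula
  base <- stats::rnorm(length(gene_names), mean = 1.0, sd = 1.0)
  base[startsWith(role, "id_")] <- stats::runif(sum(startsWith(role, "id_")),
                                                1.0, 2.5)
  # per-type log-mean profile: start from the shared baseline
  prof <- matrix(base, nrow = length(gene_names), ncol = 4,
                 dimnames = list(gene_names, types))
  for (t in types) {
    idx <- role == paste0("id_", t)
    prof[idx, t] <- prof[idx, t] + cfg$id_logfc
  }
  # hormone genes: low component everywhere except the own type's high mode
  # (single-cell draws override these per cell; bulk uses them directly)
  prof[unname(hormones), ] <- cfg$hormone_low_mean
  for (t in types) prof[hormones[[t]], t] <- cfg$hormone_high_mean
  # calibrate the mitochondrial block to the requested count fraction of the
  # expected library (non-mito expression plus one high hormone)
  lib_expect <- sum(exp(base[role == "background" | startsWith(role, "id_")])) +
    exp(cfg$hormone_high_mean)
  mito_mean <- cfg$mito_fraction_mean * lib_expect / (1 - cfg$mito_fraction_mean)
  prof[role == "mito", ] <- log(mito_mean / n_mito)
  list(gene_names = gene_names, role = role, profile = prof,
       hormones = hormones, types = types)
}

# dispersion per gene: scalar or uniform draw from a range
sim_dispersions <- function(cfg, n_genes) {
  d <- cfg$nb_dispersion
  if (length(d) == 1) rep(d, n_genes)
  else stats::runif(n_genes, min(d), max(d))
}

#' Simulate an islet single-cell UMI count matrix with ground truth
#'
#' Draws each cell's counts from negative binomial distributions around its
#' type's mean profile scaled by a per-cell library-size factor and a
#' replicate batch factor. Hormone genes are bimodal: expressing cells draw
#' from a high log-normal component, non-expressing cells from a zero-inflated
#' low component. Bihormonal cells draw BOTH of their hormones from the high
#' component and a fraction \code{id_mix_frac} of the partner type's identity
#' genes from the partner profile. Cell metadata carries the replicate, a
#' truth-derived cluster label perturbed at \code{cluster_mislabel_rate}, and
#' a sorted-fraction flag marking the gamma lineage (monohormonal gamma plus
#' bihormonal) as positive.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with \code{counts} (an \code{\link{islet_counts}}) and
#'   \code{truth}, a list holding the per-cell table (true type, hormone set,
#'   doublet flag, true cluster), the per-gene table (planted role, true
#'   ln fold changes of identity genes) and the per-type expected identity
#'   gene sets (planted identity genes plus the type's own hormone).
#' @export
simulate_sc <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  fracs <- c(cfg$type_proportions, cfg$bihorm_proportions * cfg$type_proportions[["gamma"]])
  fracs[["gamma"]] <- fracs[["gamma"]] * (1 - sum(cfg$bihorm_proportions))
  if (cfg$n_cells * min(fracs[fracs > 0]) < 10)
    stop("smallest subpopulation would have fewer than 10 expected cells")
  set.seed(cfg$seed)
  panel <- sim_gene_panel(cfg)
  G <- length(panel$gene_names)
  disp <- sim_dispersions(cfg, G)

  pop_names <- names(fracs)
  pop <- sample(pop_names, cfg$n_cells, replace = TRUE, prob = fracs)
  base_type <- ifelse(startsWith(pop, "gamma"), "gamma", pop)
  partner_of <- c(gamma_alpha = "alpha", gamma_delta = "delta",
                  gamma_beta = "beta")
  replicate <- rep_len(seq_len(cfg$n_replicates), cfg$n_cells)
  libsize <- stats::rlnorm(cfg$n_cells, cfg$libsize_mu, cfg$libsize_sigma)
  n_lowq <- round(cfg$lowq_cell_frac * cfg$n_cells)
  lowq <- rep(FALSE, cfg$n_cells)
  if (n_lowq > 0) {
    lowq[sample.int(cfg$n_cells, n_lowq)] <- TRUE
    libsize[lowq] <- libsize[lowq] * 0.01
  }
  batch <- matrix(stats::rnorm(G * cfg$n_replicates, 0, cfg$batch_effect_sd),
                  nrow = G)
  batch[, 1] <- 0 # replicate 1 is the reference batch

  hormone_genes <- panel$hormones # named by type
  hset_of <- function(p) {
    if (p %in% panel$types) unname(hormone_genes[p])
    else sort(c(hormone_genes[["gamma"]], hormone_genes[[partner_of[[p]]]]))
  }

  counts <- matrix(0L, nrow = G, ncol = cfg$n_cells,
                   dimnames = list(panel$gene_names, NULL))
  id_rows <- lapply(panel$types, function(t) which(panel$role == paste0("id_", t)))
  names(id_rows) <- panel$types
  for (c_i in seq_len(cfg$n_cells)) {
    p <- pop[c_i]
    t <- base_type[c_i]
    mu_log <- panel$profile[, t]
    if (startsWith(p, "gamma_")) {
      pt <- partner_of[[p]]
      rows <- id_rows[[pt]]
      take <- rows[seq_len(floor(cfg$id_mix_frac * length(rows)))]
      mu_log[take] <- panel$profile[take, pt]
    }
    mu <- exp(mu_log + batch[, replicate[c_i]]) * libsize[c_i]
    # hormone genes: bimodal component draw overrides the profile
    expressed <- hset_of(p)
    for (ht in panel$types) {
      hg <- hormone_genes[[ht]]
      if (hg %in% expressed) {
        mu[hg] <- exp(stats::rnorm(1, cfg$hormone_high_mean, cfg$hormone_sd)) *
          libsize[c_i]
      } else if (stats::runif(1) < cfg$hormone_dropout) {
        mu[hg] <- 0
      } else {
        mu[hg] <- exp(stats::rnorm(1, cfg$hormone_low_mean, cfg$hormone_sd)) *
          libsize[c_i]
      }
    }
    counts[, c_i] <- stats::rnbinom(G, size = 1 / disp, mu = mu)
  }

  doublet <- rep(FALSE, cfg$n_cells)
  n_dbl <- round(cfg$doublet_rate * cfg$n_cells)
  if (n_dbl > 0) {
    tgt <- sample.int(cfg$n_cells, n_dbl)
    src <- sample.int(cfg$n_cells, n_dbl, replace = TRUE)
    counts[, tgt] <- counts[, tgt] + counts[, src]
    doublet[tgt] <- TRUE
  }

  cluster_true <- ifelse(startsWith(pop, "gamma_"), "bihormonal", pop)
  cluster_obs <- cluster_true
  mis <- stats::runif(cfg$n_cells) < cfg$cluster_mislabel_rate
  all_clusters <- c(panel$types, "bihormonal")
  if (any(mis)) {
    cluster_obs[mis] <- vapply(cluster_true[mis], function(cl)
      sample(setdiff(all_clusters, cl), 1), "")
  }

  barcodes <- sprintf("cell%05d", seq_len(cfg$n_cells))
  colnames(counts) <- barcodes
  cell_meta <- data.frame(
    barcode = barcodes, replicate = replicate,
    fraction = ifelse(startsWith(pop, "gamma"), "positive", "negative"),
    cluster = cluster_obs, stringsAsFactors = FALSE)
  hormone_sets <- vapply(pop, function(p) paste(hset_of(p), collapse = "+"), "")
  truth_cells <- data.frame(
    barcode = barcodes, population = pop, base_type = base_type,
    hormones = unname(hormone_sets), cluster_true = cluster_true,
    mislabeled = mis, doublet = doublet, lowq = lowq,
    libsize = libsize, stringsAsFactors = FALSE)
  truth_genes <- data.frame(
    gene = panel$gene_names, role = panel$role,
    true_lnfc = ifelse(startsWith(panel$role, "id_"), cfg$id_logfc, 0),
    stringsAsFactors = FALSE)
  id_sets <- lapply(panel$types, function(t)
    c(panel$gene_names[panel$role == paste0("id_", t)],
      unname(hormone_genes[[t]])))
  names(id_sets) <- panel$types

  list(counts = islet_counts(counts, cell_meta = cell_meta),
       truth = list(cells = truth_cells, genes = truth_genes,
                    id_sets = id_sets, hormones = hormone_genes,
                    config = cfg))
}

#' Simulate sorted-population bulk RNA-seq counts with ground truth
#'
#' One column per sorted sample, \code{n_samples_per_type} samples for each of
#' the four monohormonal types. Gene means follow the same per-type log-mean
#' profiles as the single-cell generator (hormone genes at their high mean in
#' the own type, low mean elsewhere); counts are negative binomial with
#' log-normal per-sample size factors recorded in truth. Planted identity
#' genes are differentially expressed between gamma and every other type with
#' true log2 fold change \code{id_logfc / log(2)} >= 1 at the default
#' \code{id_logfc}.
#'
#' @param cfg A \code{\link{sim_config}}; \code{libsize_mu}/\code{libsize_sigma}
#'   act as the size-factor distribution and \code{seed} fixes the draw.
#' @param n_samples_per_type Samples per sorted population (>= 2).
#' @param depth Expected per-sample sequencing depth multiplier applied to the
#'   single-cell-scale gene means.
#' @param dispersion NB dispersion for bulk samples (scalar or range).
#'   Sorted-population biological replicates are far less overdispersed than
#'   single cells; the default 0.05 is typical of bulk RNA-seq.
#' @return A list with \code{counts} (an \code{islet_counts} of samples) and
#'   \code{truth} (per-sample type and size factor; per-gene role and true
#'   log2 fold change gamma vs each other type; per-type identity sets).
#' @export
simulate_bulk <- function(cfg = sim_config(), n_samples_per_type = 3,
                          depth = 100, dispersion = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), n_samples_per_type >= 2,
            all(dispersion > 0))
  set.seed(cfg$seed + 1L)
  panel <- sim_gene_panel(cfg)
  G <- length(panel$gene_names)
  bcfg <- cfg
  bcfg$nb_dispersion <- dispersion
  disp <- sim_dispersions(bcfg, G)
  types <- rep(panel$types, each = n_samples_per_type)
  n_s <- length(types)
  sf <- stats::rlnorm(n_s, cfg$libsize_mu, cfg$libsize_sigma)
  prof <- panel$profile
  counts <- matrix(0L, nrow = G, ncol = n_s,
                   dimnames = list(panel$gene_names,
                                   sprintf("%s_s%d", types,
                                           rep(seq_len(n_samples_per_type), 4))))
  for (s in seq_len(n_s)) {
    mu <- exp(prof[, types[s]]) * depth * sf[s]
    counts[, s] <- stats::rnbinom(G, size = 1 / disp, mu = mu)
  }
  lfc2 <- sapply(panel$types, function(t)
    (prof[, "gamma"] - prof[, t]) / log(2))
  truth_genes <- data.frame(
    gene = panel$gene_names, role = panel$role,
    true_log2fc_gamma_vs_alpha = lfc2[, "alpha"],
    true_log2fc_gamma_vs_beta = lfc2[, "beta"],
    true_log2fc_gamma_vs_delta = lfc2[, "delta"],
    stringsAsFactors = FALSE)
  id_sets <- lapply(panel$types, function(t)
    c(panel$gene_names[panel$role == paste0("id_", t)],
      unname(panel$hormones[[t]])))
  names(id_sets) <- panel$types
  cm <- data.frame(barcode = colnames(counts), cell_type = types,
                   stringsAsFactors = FALSE)
  list(counts = islet_counts(counts, cell_meta = cm),
       truth = list(samples = data.frame(sample = colnames(counts),
                                         cell_type = types, size_factor = sf,
                                         stringsAsFactors = FALSE),
                    genes = truth_genes, id_sets = id_sets, config = cfg))
}

#' Write a simulated dataset to disk
#'
#' Emits the 10x-style MTX triplet plus cell-metadata TSV via
#' \code{\link{write_counts}}, and the per-cell and per-gene truth tables as
#' TSV.
#'
#' @param sim Result of \code{\link{simulate_sc}} or
#'   \code{\link{simulate_bulk}}.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  write_counts(sim$counts, dir)
  cells <- if (!is.null(sim$truth$cells)) sim$truth$cells else sim$truth$samples
  utils::write.table(cells, file.path(dir, "truth_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
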