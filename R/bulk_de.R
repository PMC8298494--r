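#' Configuration for bulk differential expression
#'
#' @param min_mean_count Genes with a mean raw count below this value across
#'   the samples of a comparison are discarded (default 5; the boundary is
#'   retained).
#' @param lfc_call_threshold Absolute shrunken log2 fold-change call
#'   threshold (inclusive; default 1).
#' @param padj_threshold BH-adjusted p call threshold (inclusive; default
#'   0.05).
#' @param shrink_prior_sd Normal-prior SD for LFC shrinkage: a positive
#'   number, or \code{"auto"} to match the 95th percentile of the observed
#'   |MLE LFC| distribution.
#' @return A \code{bulk_de_config} list.
#' @export
bulk_de_config <- function(min_mean_count = 5, lfc_call_threshold = 1,
                           padj_threshold = 0.05, shrink_prior_sd = "auto") {
  stopifnot(min_mean_count > 0, lfc_call_threshold > 0, padj_threshold > 0)
  if (!identical(shrink_prior_sd, "auto")) stopifnot(shrink_prior_sd > 0)
  structure(list(min_mean_count = min_mean_count,
                 lfc_call_threshold = lfc_call_threshold,
                 padj_threshold = padj_threshold,
                 shrink_prior_sd = shrink_prior_sd), class = "bulk_de_config")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (expressed in
#' every sample) of the ratio of the sample's count to the gene's geometric
#' mean across samples.
#'
#' @param counts Matrix (genes x samples) of raw counts, or an
#'   \code{islet_counts}.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "islet_counts")) as.matrix(counts$counts)
       else as.matrix(counts)
  if (ncol(m) < 2) stop("need at least two samples")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene expressed in all samples")
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  sf
}

#' Mean-count gene filter for a pairwise comparison
#'
#' Keeps a gene iff its mean raw count across the given samples is at least
#' \code{min_mean_count} ("fewer than" discards strictly below the boundary).
#'
#' @param counts Genes x samples count matrix or \code{islet_counts}.
#' @param cfg A \code{\link{bulk_de_config}}.
#' @return Character vector of retained gene names.
#' @export
mean_count_filter <- function(counts, cfg = bulk_de_config()) {
  m <- if (inherits(counts, "islet_counts")) as.matrix(counts$counts)
       else as.matrix(counts)
  rownames(m)[rowMeans(m) >= cfg$min_mean_count]
}

#' Gene-wise negative binomial Wald test for bulk counts
#'
#' Per gene (after the mean-count filter), raw counts are modelled as NB with
#' a log link, a log size-factor offset and a group indicator; dispersion is
#' estimated gene-wise by maximum likelihood (Poisson fallback for
#' underdispersed fits). The Wald p-value of the group coefficient is
#' BH-adjusted across the tested genes. Positive log2 fold change means
#' higher in group A.
#'
#' @param counts Genes x samples matrix or \code{islet_counts}.
#' @param samples_a,samples_b Column names or indices of the two groups
#'   (>= 2 samples each).
#' @param cfg A \code{\link{bulk_de_config}}.
#' @param sf Optional precomputed size factors for the used samples;
#'   default recomputes on the comparison's samples.
#' @return A \code{bulk_de_result} data.frame: \code{gene},
#'   \code{base_mean} (mean of size-factor-normalized counts),
#'   \code{lfc_mle} (log2), \code{se} (log2), \code{p}, \code{padj},
#'   \code{dispersion}, \code{converged}; size factors attached as attribute
#'   \code{"size_factors"}.
#' @export
bulk_nb_wald <- function(counts, samples_a, samples_b,
                         cfg = bulk_de_config(), sf = NULL) {
  m <- if (inherits(counts, "islet_counts")) as.matrix(counts$counts)
       else as.matrix(counts)
  ia <- if (is.character(samples_a)) match(samples_a, colnames(m)) else samples_a
  ib <- if (is.character(samples_b)) match(samples_b, colnames(m)) else samples_b
  if (anyNA(c(ia, ib))) stop("unknown sample name(s)")
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least two samples per group")
  sub <- m[, c(ia, ib), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(sub)
  keep <- mean_count_filter(sub, cfg)
  if (!length(keep)) stop("no genes pass the mean-count filter")
  group <- factor(rep(c("A", "B"), c(length(ia), length(ib))),
                  levels = c("B", "A"))
  off <- log(sf)
  fit_one <- function(y) {
    dat <- data.frame(y = y, group = group, off = off)
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ group + offset(off), data = dat,
                                    control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    disp <- NA_real_
    if (!is.null(fit) && fit$converged) {
      disp <- 1 / fit$theta
    } else {
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ group + offset(off), data = dat,
                                    family = stats::poisson())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged)
        return(c(NA, NA, NA, NA, 0))
      disp <- 0
    }
    co <- summary(fit)$coefficients
    r <- grep("^groupA$", rownames(co))
    if (!length(r)) return(c(NA, NA, NA, NA, 0))
    # natural-log coefficient and SE converted to log2
    c(co[r, 1] / log(2), co[r, 2] / log(2), co[r, 4], disp, 1)
  }
  stats_m <- vapply(keep, function(g) fit_one(sub[g, ]), numeric(5))
  norm_counts <- sweep(sub[keep, , drop = FALSE], 2, sf, "/")
  out <- data.frame(gene = keep,
                    base_mean = rowMeans(norm_counts),
                    lfc_mle = stats_m[1, ], se = stats_m[2, ],
                    p = stats_m[3, ],
                    padj = stats::p.adjust(stats_m[3, ], method = "BH"),
                    dispersion = stats_m[4, ],
                    converged = stats_m[5, ] == 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "size_factors") <- sf
  class(out) <- c("bulk_de_result", "data.frame")
  out
}

#' Shrink log2 fold changes under a zero-centered normal prior
#'
#' Posterior-mode shrinkage:
#' \code{lfc_shrunk = lfc_mle * prior_var / (prior_var + se^2)}. The prior
#' variance is fixed by the config, or chosen by the \code{"auto"} rule that
#' matches the prior's 95th percentile to the 95th percentile of the observed
#' |MLE LFC|. Shrinkage contracts every estimate toward zero and never flips
#' its sign.
#'
#' @param res A \code{bulk_de_result} from \code{\link{bulk_nb_wald}}.
#' @param cfg A \code{\link{bulk_de_config}}.
#' @return The result with columns \code{lfc_shrunk} added and the chosen
#'   \code{prior_sd} attached as an attribute.
#' @export
shrink_lfc_normal <- function(res, cfg = bulk_de_config()) {
  stopifnot(inherits(res, "bulk_de_result"))
  if (identical(cfg$shrink_prior_sd, "auto")) {
    q95 <- stats::quantile(abs(res$lfc_mle[res$converged]), 0.95, na.rm = TRUE)
    prior_sd <- max(as.numeric(q95) / stats::qnorm(0.975), 1e-6)
  } else prior_sd <- cfg$shrink_prior_sd
  pv <- prior_sd^2
  shrunk <- res$lfc_mle * pv / (pv + res$se^2)
  shrunk[is.na(res$se)] <- NA_real_
  res$lfc_shrunk <- shrunk
  attr(res, "prior_sd") <- prior_sd
  res
}

#' Call differentially expressed genes from shrunken results
#'
#' A gene is called iff \code{|lfc_shrunk| >= lfc_call_threshold} and
#' \code{padj <= padj_threshold}; both boundaries are inclusive.
#'
#' @param res Shrunken \code{bulk_de_result}
#'   (\code{\link{shrink_lfc_normal}}).
#' @param cfg A \code{\link{bulk_de_config}}.
#' @param direction \code{"both"}, \code{"up"} (positive LFC only) or
#'   \code{"down"}.
#' @return Character vector of called genes.
#' @export
call_de <- function(res, cfg = bulk_de_config(),
                    direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (is.null(res$lfc_shrunk)) stop("run shrink_lfc_normal first")
  lfc <- res$lfc_shrunk
  ok <- !is.na(lfc) & !is.na(res$padj) &
    abs(lfc) >= cfg$lfc_call_threshold & res$padj <= cfg$padj_threshold
  if (direction == "up") ok <- ok & lfc > 0
  if (direction == "down") ok <- ok & lfc < 0
  res$gene[ok]
}

#' End-to-end bulk pairwise DE
#'
#' Mean-count filter, NB Wald test, normal-prior shrinkage and DE calls in
#' one step.
#'
#' @inheritParams bulk_nb_wald
#' @return The shrunken \code{bulk_de_result} with a logical \code{called}
#'   column added.
#' @export
bulk_de_pairwise <- function(counts, samples_a, samples_b,
                             cfg = bulk_de_config()) {
  res <- bulk_nb_wald(counts, samples_a, samples_b, cfg)
  res <- shrink_lfc_normal(res, cfg)
  called <- call_de(res, cfg)
  res$called <- res$gene %in% called
  res
}

#' Read a bulk count table with its sample sheet
#'
#' @param counts_path Gene x sample TSV with a header of sample names and
#'   gene names in the first column.
#' @param sample_sheet_path TSV with columns \code{sample} and
#'   \code{cell_type}.
#' @return An \code{islet_counts} whose \code{cell_meta} carries the sample
#'   sheet.
#' @export
read_bulk_counts <- function(counts_path, sample_sheet_path) {
  tab <- utils::read.delim(counts_path, row.names = 1, check.names = FALSE)
  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "cell_type") %in% names(sheet)))
  if (!setequal(colnames(tab), sheet$sample))
    stop("sample sheet does not match count table columns")
  sheet <- sheet[match(colnames(tab), sheet$sample), ]
  cm <- data.frame(barcode = sheet$sample, cell_type = sheet$cell_type,
                   stringsAsFactors = FALSE)
  islet_counts(as.matrix(tab), cell_meta = cm)
}
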