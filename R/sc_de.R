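#' Configuration for pairwise single-cell differential expression
#'
#' @param min_logfc Natural-log fold-change floor for the pre-filter
#'   (default 0.5).
#' @param covariates Nuisance covariates regressed out in the NB GLM; any
#'   subset of \code{c("replicate", "n_umis", "n_genes")}. Default is the
#'   full set (each is dropped automatically if constant).
#' @param alpha Adjusted-p cutoff for significance calls.
#' @param pseudocount Pseudocount in the fold-change formula.
#' @param min_detect_frac Optional minimum fraction of expressing cells in at
#'   least one group for a gene to be tested (default 0 = off).
#' @return A \code{de_config} list.
#' @export
de_config <- function(min_logfc = 0.5,
                      covariates = c("replicate", "n_umis", "n_genes"),
                      alpha = 0.05, pseudocount = 1, min_detect_frac = 0) {
  stopifnot(min_logfc >= 0, alpha > 0, alpha < 1, pseudocount >= 0,
            min_detect_frac >= 0, min_detect_frac <= 1,
            all(covariates %in% c("replicate", "n_umis", "n_genes")))
  structure(list(min_logfc = min_logfc, covariates = covariates,
                 alpha = alpha, pseudocount = pseudocount,
                 min_detect_frac = min_detect_frac), class = "de_config")
}

#' Log fold-change pre-filter between two cell groups
#'
#' The fold change is computed on the normalized scale as
#' \code{ln((mean_A(expm1(value)) + pc) / (mean_B(expm1(value)) + pc))};
#' genes whose absolute value falls below \code{min_logfc} are excluded from
#' model-based testing.
#'
#' @param nm An \code{islet_norm} matrix.
#' @param cells_a,cells_b Barcodes (or column indices) of the two disjoint,
#'   non-empty groups.
#' @param cfg A \code{\link{de_config}}.
#' @return data.frame of all genes with \code{logfc}, \code{mean_a},
#'   \code{mean_b} (expm1-scale means), \code{pct_a}, \code{pct_b}
#'   (expressing fractions) and logical \code{candidate}.
#' @export
prefilter_logfc <- function(nm, cells_a, cells_b, cfg = de_config()) {
  stopifnot(inherits(nm, "islet_norm"))
  ia <- .resolve_cells(nm$values, cells_a)
  ib <- .resolve_cells(nm$values, cells_b)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  va <- nm$values[, ia, drop = FALSE]
  vb <- nm$values[, ib, drop = FALSE]
  mean_a <- Matrix::rowSums(expm1(va)) / length(ia)
  mean_b <- Matrix::rowSums(expm1(vb)) / length(ib)
  logfc <- log((mean_a + cfg$pseudocount) / (mean_b + cfg$pseudocount))
  pct_a <- Matrix::rowSums(va > 0) / length(ia)
  pct_b <- Matrix::rowSums(vb > 0) / length(ib)
  cand <- abs(logfc) >= cfg$min_logfc
  if (cfg$min_detect_frac > 0)
    cand <- cand & pmax(pct_a, pct_b) >= cfg$min_detect_frac
  data.frame(gene = rownames(nm$values), logfc = logfc,
             mean_a = mean_a, mean_b = mean_b,
             pct_a = pct_a, pct_b = pct_b, candidate = cand,
             row.names = NULL, stringsAsFactors = FALSE)
}

.resolve_cells <- function(mat, cells) {
  if (is.character(cells)) {
    i <- match(cells, colnames(mat))
    if (anyNA(i)) stop("unknown cell barcode(s)")
    i
  } else if (is.logical(cells)) which(cells) else as.integer(cells)
}

#' Negative binomial GLM test for candidate genes
#'
#' Per candidate gene, raw counts are regressed on the group indicator plus
#' the configured nuisance covariates under a negative binomial GLM with log
#' link (gene-wise ML dispersion). The reported p-value is the Wald test of
#' the group coefficient, Bonferroni-adjusted against the total number of
#' genes in the dataset (not just the candidates). Genes whose NB fit fails
#' fall back to the Poisson limit; genes failing both are flagged with
#' \code{p = NA} and never enter significant sets.
#'
#' @param m The full \code{islet_counts} object (raw counts; also supplies
#'   the per-cell covariates and the Bonferroni denominator).
#' @param cells_a,cells_b Disjoint, non-empty cell groups (barcodes or
#'   indices).
#' @param prefilter Result of \code{\link{prefilter_logfc}} on the same
#'   groups; only rows with \code{candidate = TRUE} are tested.
#' @param cfg A \code{\link{de_config}}.
#' @return A \code{de_result} data.frame: per candidate gene \code{logfc}
#'   (natural log, from the pre-filter), \code{p}, \code{p_adj}, group means
#'   and expressing fractions, \code{converged}; attribute
#'   \code{n_total_genes} records the Bonferroni denominator.
#' @export
nb_glm_test <- function(m, cells_a, cells_b, prefilter, cfg = de_config()) {
  stopifnot(inherits(m, "islet_counts"))
  ia <- .resolve_cells(m$counts, cells_a)
  ib <- .resolve_cells(m$counts, cells_b)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  cand <- prefilter[prefilter$candidate, , drop = FALSE]
  if (!nrow(cand)) stop("candidate list is empty")
  cells <- c(ia, ib)
  group <- factor(rep(c("A", "B"), c(length(ia), length(ib))),
                  levels = c("B", "A")) # coef is the A effect
  covs <- data.frame(group = group)
  totals <- Matrix::colSums(m$counts[, cells, drop = FALSE])
  nfeat <- Matrix::colSums(m$counts[, cells, drop = FALSE] > 0)
  if ("n_umis" %in% cfg$covariates) covs$n_umis <- log(totals)
  if ("n_genes" %in% cfg$covariates) covs$n_genes <- log(nfeat)
  if ("replicate" %in% cfg$covariates && !is.null(m$cell_meta$replicate))
    covs$replicate <- factor(m$cell_meta$replicate[cells])
  # drop constant covariates (e.g. a single replicate)
  keep <- vapply(covs, function(x) length(unique(x)) > 1, TRUE)
  covs <- covs[, keep | names(covs) == "group", drop = FALSE]
  form <- stats::as.formula(paste("y ~", paste(names(covs), collapse = " + ")))
  sub <- as.matrix(m$counts[cand$gene, cells, drop = FALSE])
  n_genes_total <- nrow(m$counts)
  res <- vapply(seq_len(nrow(cand)), function(i) {
    dat <- covs
    dat$y <- sub[i, ]
    .nb_wald_one(form, dat)
  }, c(p = 0, converged = 0))
  p <- res["p", ]
  out <- data.frame(gene = cand$gene, logfc = cand$logfc, p = p,
                    p_adj = pmin(1, p * n_genes_total),
                    mean_a = cand$mean_a, mean_b = cand$mean_b,
                    pct_a = cand$pct_a, pct_b = cand$pct_b,
                    converged = res["converged", ] == 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "n_total_genes") <- n_genes_total
  class(out) <- c("de_result", "data.frame")
  out
}

# Wald p for the group coefficient: NB GLM with ML dispersion, Poisson
# fallback in the no-overdispersion limit, NA when both fail.
.nb_wald_one <- function(form, dat) {
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, data = dat, family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(p = NA_real_, converged = 0))
  }
  co <- summary(fit)$coefficients
  row <- grep("^groupA$", rownames(co))
  if (!length(row)) return(c(p = NA_real_, converged = 0))
  c(p = co[row, 4], converged = 1)
}

#' Extract the upregulated gene set from a DE result
#'
#' Genes with \code{logfc >= min_logfc} and \code{p_adj <= alpha}, ordered by
#' descending log fold change. Non-converged genes (\code{p = NA}) are never
#' included.
#'
#' @param res A \code{de_result}.
#' @param cfg A \code{\link{de_config}}.
#' @return Character vector of gene names.
#' @export
upregulated_set <- function(res, cfg = de_config()) {
  ok <- !is.na(res$p_adj) & res$logfc >= cfg$min_logfc & res$p_adj <= cfg$alpha
  res$gene[ok][order(res$logfc[ok], decreasing = TRUE)]
}

#' One-call pairwise single-cell DE between two identity groups
#'
#' Runs \code{\link{prefilter_logfc}} then \code{\link{nb_glm_test}} for the
#' cells carrying two identity labels in a \code{cell_identity} table
#' (retained cells only).
#'
#' @param m Raw \code{islet_counts}.
#' @param nm Matching \code{islet_norm}.
#' @param ids \code{cell_identity} table (after consistency filtering).
#' @param label_a,label_b Identity labels to compare (A vs B; positive logfc
#'   means higher in A).
#' @param cfg A \code{\link{de_config}}.
#' @return A \code{de_result}.
#' @export
sc_de_pairwise <- function(m, nm, ids, label_a, label_b, cfg = de_config()) {
  ca <- ids$barcode[ids$retained & ids$identity == label_a]
  cb <- ids$barcode[ids$retained & ids$identity == label_b]
  if (!length(ca)) stop("no retained cells with identity ", label_a)
  if (!length(cb)) stop("no retained cells with identity ", label_b)
  pf <- prefilter_logfc(nm, ca, cb, cfg)
  nb_glm_test(m, ca, cb, pf, cfg)
}
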