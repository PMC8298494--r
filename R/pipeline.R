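#' Default cluster-to-identity map for the simulated islet
#'
#' Monohormonal clusters map to their hormone identity; the hybrid cluster is
#' tagged \code{"bihormonal"}.
#'
#' @return Named character vector usable by
#'   \code{\link{cluster_consistency_filter}}.
#' @export
default_cluster_map <- function() {
  c(alpha = "Gcg", beta = "Ins2", delta = "Sst", gamma = "Ppy",
    bihormonal = "bihormonal")
}

#' Run the full single-cell identity pipeline
#'
#' QC filtering, log-normalization, antimode hormone gating, identity
#' assignment, cluster-consistency filtering, pairwise NB DE of the anchor
#' type against the other monohormonal types, anchor identity-set
#' derivation, and hybrid-identity overlap of each bihormonal population
#' against the partner type's identity set.
#'
#' @param m Raw \code{islet_counts} (e.g. from \code{\link{simulate_sc}}).
#' @param hormones Named character vector mapping cell types to hormone
#'   genes; default mouse islet panel.
#' @param anchor Anchor hormone whose mono- and bihormonal populations are
#'   profiled (default \code{"Ppy"}).
#' @param cluster_map Cluster-to-identity map.
#' @param qc A \code{\link{qc_config}}.
#' @param de A \code{\link{de_config}}.
#' @param scale_factor Normalization scale factor.
#' @param partner_ids Derive partner-type identity sets too (needed for the
#'   bihormonal overlaps; default TRUE).
#' @return List with \code{qc} (filtered counts), \code{norm},
#'   \code{thresholds}, \code{identity} (per-cell table), \code{de}
#'   (pairwise \code{de_result}s of anchor vs others), \code{id_set}
#'   (anchor identity set), \code{partner_id_sets}, \code{bihorm_de},
#'   \code{overlaps} (per bihormonal population) and \code{shares}
#'   (bihormonal composition of the anchor pool).
#' @export
islet_pipeline <- function(m,
                           hormones = c(alpha = "Gcg", beta = "Ins2",
                                        delta = "Sst", gamma = "Ppy"),
                           anchor = "Ppy",
                           cluster_map = default_cluster_map(),
                           qc = qc_config(), de = de_config(),
                           scale_factor = 10000, partner_ids = TRUE) {
  mq <- qc_filter(m, qc)
  nm <- log_normalize(mq, scale_factor)
  thr <- hormone_thresholds(nm, unname(hormones))
  status <- assign_hormone_status(nm, thr)
  ids <- assign_identity(status, mq$cell_meta)
  ids <- cluster_consistency_filter(ids, cluster_map, anchor = anchor)

  others <- setdiff(unname(hormones), anchor)
  de_res <- lapply(others, function(h)
    sc_de_pairwise(mq, nm, ids, anchor, h, de))
  names(de_res) <- paste0(anchor, "_vs_", others)
  up <- lapply(de_res, upregulated_set, cfg = de)
  id_set <- derive_id_genes(up, type = anchor, comparisons = names(de_res))

  partner_sets <- NULL
  if (partner_ids) {
    partner_sets <- lapply(others, function(h) {
      rest <- setdiff(unname(hormones), h)
      ups <- lapply(rest, function(o) {
        r <- sc_de_pairwise(mq, nm, ids, h, o, de)
        upregulated_set(r, de)
      })
      derive_id_genes(ups, type = h,
                      comparisons = paste0(h, "_vs_", rest))
    })
    names(partner_sets) <- others
  }

  # bihormonal populations of the anchor pool, in canonical label form
  bi_labels <- vapply(others, function(h)
    paste(sort(c(anchor, h)), collapse = "+"), "")
  present <- vapply(bi_labels, function(l)
    sum(ids$retained & ids$identity == l) > 0, TRUE)
  bihorm_de <- list(); overlaps <- list()
  for (i in which(present)) {
    l <- bi_labels[i]
    r <- sc_de_pairwise(mq, nm, ids, l, anchor, de)
    bihorm_de[[l]] <- r
    if (partner_ids)
      overlaps[[l]] <- bihormonal_overlap(upregulated_set(r, de),
                                          partner_sets[[others[i]]])
  }

  pool <- ids$retained & grepl(anchor, ids$identity, fixed = TRUE)
  shares <- table(factor(ids$identity[pool], levels = c(anchor, bi_labels)))
  list(qc = mq, norm = nm, thresholds = thr, identity = ids,
       de = de_res, id_set = id_set, partner_id_sets = partner_sets,
       bihorm_de = bihorm_de, overlaps = overlaps,
       shares = shares)
}
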