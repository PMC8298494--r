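#' Kernel density of normalized expression for one gene
#'
#' Gaussian-kernel density of a hormone's log-normalized expression across
#' all cells of the dataset, including zeros (the non-expressing mass forms
#' the left mode). Bandwidth is Silverman's rule unless overridden; the grid
#' is evenly spaced with at least 512 points and covers the observed range
#' (extended by the usual three bandwidths, so it spans [0, max]).
#'
#' @param values Numeric vector of normalized expression across all cells.
#' @param bandwidth Either \code{"silverman"} or a positive numeric bandwidth.
#' @param n_grid Number of grid points (>= 512).
#' @return A \code{density_curve}: list with \code{grid}, \code{density} and
#'   \code{bandwidth}.
#' @export
estimate_density <- function(values, bandwidth = "silverman", n_grid = 512) {
  values <- as.numeric(values)
  if (length(values) < 100)
    stop("need at least 100 values for a reliable density threshold")
  if (anyNA(values)) stop("values contain NA")
  if (max(values) == min(values))
    stop("degenerate distribution: all values identical")
  n_grid <- max(512, n_grid)
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
        else as.numeric(bandwidth)
  stopifnot(bw > 0)
  d <- stats::density(values, bw = bw, n = n_grid, kernel = "gaussian")
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "density_curve")
}

#' Locate the antimode (threshold) of a bimodal density
#'
#' Local maxima are found by the sign change of the first difference of the
#' density; the two highest-density maxima are the principal modes. The
#' threshold is the grid point of minimum density strictly between them, and
#' the bimodality amplitude is \code{(h_low - h_anti) / h_low}, with
#' \code{h_low} the smaller principal-mode height and \code{h_anti} the
#' antimode height.
#'
#' @param curve A \code{density_curve} from \code{\link{estimate_density}}.
#' @param amplitude_floor Amplitudes at or below this value are flagged as
#'   low-confidence (the threshold is still returned).
#' @param mode_floor Local maxima with height below this fraction of the
#'   global peak are treated as finite-sample wiggles, not modes (guards the
#'   unimodality check against kernel-tail noise).
#' @return A \code{hormone_threshold}: list with \code{threshold},
#'   \code{amplitude}, \code{modes} (data.frame of the two principal modes'
#'   locations and heights), \code{antimode_height} and
#'   \code{low_confidence}.
#' @export
find_antimode <- function(curve, amplitude_floor = 0.05, mode_floor = 0.01) {
  stopifnot(inherits(curve, "density_curve"))
  y <- curve$density
  x <- curve$grid
  d1 <- diff(y)
  s <- sign(d1)
  # interior maxima: slope changes from positive to negative
  is_max <- which(s[-length(s)] > 0 & s[-1] <= 0) + 1L
  # endpoints can carry a mode if the density is already falling/rising there
  if (length(s) && s[1] < 0) is_max <- c(1L, is_max)
  if (length(s) && s[length(s)] > 0) is_max <- c(is_max, length(y))
  is_max <- is_max[y[is_max] >= mode_floor * max(y)]
  if (length(is_max) < 2)
    stop("density is unimodal: no antimode between modes ",
         "(widen the bandwidth or abort)")
  top2 <- is_max[order(y[is_max], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  inner <- (lo + 1L):(hi - 1L)
  if (length(inner) < 1) stop("principal modes are adjacent; no interior grid point")
  anti <- inner[which.min(y[inner])]
  h_low <- min(y[top2])
  amp <- (h_low - y[anti]) / h_low
  res <- structure(list(
    threshold = x[anti], amplitude = amp,
    modes = data.frame(location = x[sort(top2)], height = y[sort(top2)]),
    antimode_height = y[anti],
    low_confidence = amp <= amplitude_floor), class = "hormone_threshold")
  if (res$low_confidence)
    warning(sprintf("bimodality amplitude %.3f at or below floor %.2f: threshold is low-confidence",
                    amp, amplitude_floor))
  res
}

#' @exportS3Method base::print
print.hormone_threshold <- function(x, ...) {
  cat(sprintf("antimode threshold %.4f (amplitude %.3f%s)\n", x$threshold,
              x$amplitude, if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  cat(sprintf("  principal modes at %.4f (h=%.3f) and %.4f (h=%.3f)\n",
              x$modes$location[1], x$modes$height[1],
              x$modes$location[2], x$modes$height[2]))
  invisible(x)
}

#' Derive antimode thresholds for a set of hormone genes
#'
#' Convenience wrapper: one density + antimode per hormone gene, computed on
#' the pooled normalized expression of the entire dataset.
#'
#' @param nm An \code{islet_norm} matrix.
#' @param hormones Character vector of hormone gene names present in the
#'   matrix.
#' @param bandwidth,n_grid,amplitude_floor Passed through to
#'   \code{\link{estimate_density}} / \code{\link{find_antimode}}.
#' @return Named list of \code{hormone_threshold} objects, with the density
#'   curve attached as \code{$curve}.
#' @export
hormone_thresholds <- function(nm, hormones, bandwidth = "silverman",
                               n_grid = 512, amplitude_floor = 0.05) {
  stopifnot(inherits(nm, "islet_norm"))
  missing <- setdiff(hormones, rownames(nm$values))
  if (length(missing))
    stop("hormone gene(s) not in matrix: ", paste(missing, collapse = ", "))
  out <- lapply(hormones, function(h) {
    curve <- estimate_density(as.numeric(nm$values[h, ]), bandwidth, n_grid)
    th <- find_antimode(curve, amplitude_floor)
    th$curve <- curve
    th
  })
  names(out) <- hormones
  out
}

#' Assign per-cell hormone expression status
#'
#' A cell expresses a hormone iff its normalized expression is strictly
#' higher than that hormone's antimode threshold (ties resolve to
#' non-expressing).
#'
#' @param nm An \code{islet_norm} matrix.
#' @param thresholds Named list from \code{\link{hormone_thresholds}}, or a
#'   named numeric vector of threshold values.
#' @return Logical matrix, hormones x cells.
#' @export
assign_hormone_status <- function(nm, thresholds) {
  stopifnot(inherits(nm, "islet_norm"))
  thr <- if (is.numeric(thresholds)) thresholds
         else vapply(thresholds, function(t) t$threshold, 0)
  missing <- setdiff(names(thr), rownames(nm$values))
  if (length(missing))
    stop("hormone gene(s) not in matrix: ", paste(missing, collapse = ", "))
  status <- as.matrix(nm$values[names(thr), , drop = FALSE]) > thr
  status
}

#' Derive per-cell identities from hormone status
#'
#' The identity label is the sorted "+"-joined concatenation of the expressed
#' hormones; the empty set maps to \code{"none"} and is flagged non-endocrine
#' (excluded from downstream analysis).
#'
#' @param status Logical hormones x cells matrix from
#'   \code{\link{assign_hormone_status}}.
#' @param cell_meta Optional per-cell data.frame carrying \code{cluster}
#'   labels to join.
#' @return A \code{cell_identity} data.frame: \code{barcode},
#'   \code{identity}, \code{n_hormones}, \code{endocrine}, and
#'   \code{cluster}/other metadata when supplied; \code{retained} is
#'   initialised to \code{endocrine} and refined by
#'   \code{\link{cluster_consistency_filter}}.
#' @export
assign_identity <- function(status, cell_meta = NULL) {
  hs <- rownames(status)
  labels <- apply(status, 2, function(col) {
    e <- sort(hs[col])
    if (!length(e)) "none" else paste(e, collapse = "+")
  })
  out <- data.frame(barcode = colnames(status), identity = unname(labels),
                    n_hormones = unname(colSums(status)),
                    stringsAsFactors = FALSE)
  out$endocrine <- out$identity != "none"
  if (!is.null(cell_meta)) {
    add <- cell_meta[match(out$barcode, cell_meta$barcode),
                     setdiff(names(cell_meta), names(out)), drop = FALSE]
    out <- cbind(out, add)
  }
  out$retained <- out$endocrine
  out$exclude_reason <- ifelse(out$endocrine, "", "non_endocrine")
  class(out) <- c("cell_identity", "data.frame")
  out
}

#' Display an identity label anchored on one hormone
#'
#' Canonical labels are alphabetically sorted (\code{"Gcg+Ppy"}); views
#' anchored on a hormone of interest list it first (\code{"Ppy+Gcg"}).
#'
#' @param identity Character vector of canonical identity labels.
#' @param anchor Hormone to list first where present.
#' @return Character vector of display labels.
#' @export
anchored_label <- function(identity, anchor = "Ppy") {
  vapply(strsplit(identity, "+", fixed = TRUE), function(hs) {
    if (anchor %in% hs) paste(c(anchor, setdiff(hs, anchor)), collapse = "+")
    else paste(hs, collapse = "+")
  }, "")
}

#' Filter assigned identities for cluster consistency
#'
#' Monohormonal cells are retained only when their identity matches their
#' cluster's expected cell type; bihormonal cells containing the anchor
#' hormone are retained only inside the designated bihormonal cluster.
#' Everything else (non-endocrine cells, bihormonal cells outside the
#' bihormonal cluster, identities inconsistent with their cluster) is marked
#' \code{retained = FALSE} with the reason recorded.
#'
#' @param ids A \code{cell_identity} table with a \code{cluster} column.
#' @param cluster_map Named character vector mapping every cluster label to
#'   its expected monohormonal identity (a hormone gene name), or to
#'   \code{"bihormonal"} for the hybrid cluster.
#' @param anchor Hormone anchoring the bihormonal definition (default
#'   \code{"Ppy"}).
#' @return The table with \code{retained} and \code{exclude_reason} updated.
#' @export
cluster_consistency_filter <- function(ids, cluster_map, anchor = "Ppy") {
  if (is.null(ids$cluster) || anyNA(ids$cluster))
    stop("every cell needs a cluster label")
  unmapped <- setdiff(unique(ids$cluster), names(cluster_map))
  if (length(unmapped))
    stop("unmapped cluster label(s): ", paste(unmapped, collapse = ", "))
  expected <- unname(cluster_map[ids$cluster])
  bihorm_cluster <- expected == "bihormonal"
  is_bihorm <- ids$n_hormones == 2 &
    vapply(strsplit(ids$identity, "+", fixed = TRUE),
           function(h) anchor %in% h, TRUE)
  retained <- rep(FALSE, nrow(ids))
  reason <- ids$exclude_reason
  mono_ok <- ids$n_hormones == 1 & ids$identity == expected
  bi_ok <- is_bihorm & bihorm_cluster
  retained[mono_ok | bi_ok] <- TRUE
  reason[!ids$endocrine] <- "non_endocrine"
  reason[ids$endocrine & !retained & ids$n_hormones == 1] <- "cluster_mismatch"
  reason[ids$endocrine & !retained & is_bihorm] <- "bihormonal_outside_cluster"
  reason[ids$endocrine & !retained & ids$n_hormones >= 2 & !is_bihorm] <-
    "multihormonal_non_anchor"
  retained[!ids$endocrine] <- FALSE
  ids$retained <- retained
  ids$exclude_reason <- ifelse(retained, "", reason)
  ids
}

#' Write a per-hormone threshold report
#'
#' JSON report of threshold, amplitude, mode locations/heights and confidence
#' per hormone; optionally dumps each density curve as TSV alongside.
#'
#' @param thresholds Named list from \code{\link{hormone_thresholds}}.
#' @param path Output JSON path.
#' @param curves_dir Optional directory for per-hormone density TSV dumps.
#' @return Invisibly, \code{path}.
#' @export
write_threshold_report <- function(thresholds, path, curves_dir = NULL) {
  rep <- lapply(thresholds, function(t) list(
    threshold = t$threshold, amplitude = t$amplitude,
    mode_locations = t$modes$location, mode_heights = t$modes$height,
    antimode_height = t$antimode_height, low_confidence = t$low_confidence,
    bandwidth = if (!is.null(t$curve)) t$curve$bandwidth else NULL))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curves_dir)) {
    if (!dir.exists(curves_dir)) dir.create(curves_dir, recursive = TRUE)
    for (h in names(thresholds)) {
      cv <- thresholds[[h]]$curve
      if (!is.null(cv))
        utils::write.table(
          data.frame(grid = cv$grid, density = cv$density),
          file.path(curves_dir, paste0(h, "_density.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
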