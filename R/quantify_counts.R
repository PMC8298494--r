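#' Read a scored-cell count table
#'
#' Rows of (unit, category, numerator, denominator) where the unit is a
#' biological replicate (animal, donor or dataset) and the counts come from
#' scored cells (e.g. figure-legend tallies).
#'
#' @param path TSV with header columns \code{unit}, \code{category},
#'   \code{numerator}, \code{denominator}.
#' @return A validated \code{scored_counts} data.frame.
#' @export
read_scored_counts <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  scored_counts(t)
}

#' Validate a scored-cell count table
#'
#' @param t data.frame with columns \code{unit}, \code{category},
#'   \code{numerator}, \code{denominator}.
#' @return The table with class \code{scored_counts}.
#' @export
scored_counts <- function(t) {
  stopifnot(all(c("unit", "category", "numerator", "denominator") %in% names(t)))
  if (any(t$numerator < 0) || any(t$numerator > t$denominator))
    stop("need 0 <= numerator <= denominator")
  class(t) <- c("scored_counts", "data.frame")
  t
}

# one-decimal truncation (floor), one-decimal rounding, integer rounding
.fmt_pct <- function(x, format) {
  switch(format,
         truncate1 = floor(x * 10 + 1e-9) / 10,
         round1 = round(x, 1),
         round0 = round(x),
         stop("unknown format: ", format))
}

#' Pooled category shares of a scored-cell table
#'
#' In \code{share_of_total} mode the categories are taken to partition one
#' pool and each share is its numerator over the summed numerators; in
#' \code{share_of_denominator} mode each row's share is numerator over its
#' own denominator (pooled across units per category). Shares are formatted
#' by one-decimal truncation (the default for scRNA-seq-derived shares),
#' one-decimal rounding or integer rounding; the raw percentage is always
#' retained.
#'
#' @param t A \code{scored_counts} table.
#' @param mode \code{"share_of_total"} or \code{"share_of_denominator"}.
#' @param format \code{"truncate1"}, \code{"round1"} or \code{"round0"}.
#' @return data.frame per category: \code{numerator}, \code{denominator},
#'   \code{pct_raw} and \code{pct} (formatted).
#' @export
category_share <- function(t, mode = c("share_of_total", "share_of_denominator"),
                           format = c("truncate1", "round1", "round0")) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  t <- scored_counts(t)
  if (!nrow(t)) stop("empty table")
  num <- tapply(t$numerator, t$category, sum)
  den <- tapply(t$denominator, t$category, sum)
  cats <- unique(t$category) # preserve input order
  num <- num[cats]; den <- den[cats]
  if (mode == "share_of_total") {
    total <- sum(num)
    if (total == 0) stop("zero total count")
    pct <- 100 * num / total
    den_out <- rep(total, length(cats))
  } else {
    if (any(den == 0)) stop("zero denominator")
    pct <- 100 * num / den
    den_out <- den
  }
  data.frame(category = cats, numerator = as.integer(num),
             denominator = as.integer(den_out),
             pct_raw = as.numeric(pct), pct = .fmt_pct(as.numeric(pct), format),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-unit percentages with mean and s.e.m.
#'
#' Computes each biological unit's percentage (numerator over denominator,
#' summed within unit and category), then the across-unit arithmetic mean and
#' standard error of the mean (sample SD / sqrt(n); \code{NA} for a single
#' unit).
#'
#' @param t A \code{scored_counts} table.
#' @return List with \code{per_unit} (unit x category percentages) and
#'   \code{summary} (per category: \code{mean}, \code{sem}, \code{n_units}).
#' @export
per_unit_stats <- function(t) {
  t <- scored_counts(t)
  if (!nrow(t)) stop("empty table")
  agg <- stats::aggregate(cbind(numerator, denominator) ~ unit + category,
                          data = t, FUN = sum)
  agg$pct <- 100 * agg$numerator / agg$denominator
  summ <- do.call(rbind, lapply(split(agg, agg$category), function(g) {
    n <- nrow(g)
    data.frame(category = g$category[1], mean = mean(g$pct),
               sem = if (n > 1) stats::sd(g$pct) / sqrt(n) else NA_real_,
               n_units = n, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_unit = agg[, c("unit", "category", "numerator", "denominator", "pct")],
       summary = summ)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration of all group assignments for combined n <= 12 (ties
#' handled with mid-ranks; the two-sided p is the probability, over all
#' equally likely assignments, of a U statistic at least as far from its null
#' mean as observed). Larger samples use the normal approximation with tie
#' and continuity corrections.
#'
#' @param group_a,group_b Numeric vectors (e.g. per-unit percentages), each
#'   of length >= 1.
#' @param exact_max Combined-size limit for exact enumeration.
#' @return List with \code{p}, the observed \code{u} (for group A),
#'   \code{method} (\code{"exact"} or \code{"normal"}).
#' @export
mann_whitney_two_sided <- function(group_a, group_b, exact_max = 12) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  pooled <- c(group_a, group_b)
  r <- rank(pooled) # mid-ranks for ties
  u_of <- function(idx_a) sum(r[idx_a]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, n1)
    us <- apply(combs, 2, u_of)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    return(list(p = p, u = u_obs, method = "exact"))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(p = 1, u = u_obs, method = "normal"))
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(p = min(1, 2 * stats::pnorm(-z)), u = u_obs, method = "normal")
}
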