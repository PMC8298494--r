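# Shared fixtures and independent oracles used across test files.

# small but well-populated simulation config (every subpopulation >= 10 cells)
small_sim_config <- function(seed = 42, ...) {
  args <- utils::modifyList(list(n_cells = 2500, n_genes = 800,
                                 n_id_genes_per_type = 10, seed = seed),
                            list(...))
  do.call(sim_config, args)
}

# a tiny islet_counts built by hand
toy_counts <- function(mat = NULL) {
  if (is.null(mat)) {
    mat <- matrix(c(5, 0, 0, 0, 0, 2), nrow = 3, byrow = TRUE,
                  dimnames = list(c("Ppy", "mt-Nd1", "Gcg"), c("c1", "c2")))
  }
  islet_counts(mat)
}

# null scRNA-seq counts: two groups drawn from one NB population
null_counts <- function(n_genes, n_per_group, seed, dispersion = 0.3) {
  set.seed(seed)
  mu <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1)
  n <- 2 * n_per_group
  m <- matrix(stats::rnbinom(n_genes * n, size = 1 / dispersion, mu = mu),
              nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%04d", seq_len(n))))
  islet_counts(m)
}

# brute-force interior-minimum oracle for the antimode: scan all grid points
# strictly between the two highest local maxima (maxima found independently
# by comparing each point with its neighbours)
oracle_antimode <- function(curve, mode_floor = 0.01) {
  y <- curve$density
  n <- length(y)
  loc_max <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || y[i] >= y[i - 1]
    right_ok <- i == n || y[i] >= y[i + 1]
    strict <- (i > 1 && y[i] > y[i - 1]) || (i < n && y[i] > y[i + 1])
    loc_max[i] <- left_ok && right_ok && strict
  }
  idx <- which(loc_max & y >= mode_floor * max(y))
  if (length(idx) < 2) return(NULL)
  top2 <- sort(idx[order(y[idx], decreasing = TRUE)[1:2]])
  interior <- (top2[1] + 1):(top2[2] - 1)
  best <- interior[1]
  for (i in interior) if (y[i] < y[best]) best <- i
  curve$grid[best]
}

# exhaustive Mann-Whitney oracle: U from pairwise comparisons (not rank
# sums); two-sided p over all assignments of the pooled values
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_stat <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y)
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  mu <- n1 * (n - n1) / 2
  u_obs <- u_stat(a, b)
  splits <- utils::combn(n, n1)
  extreme <- 0
  for (k in seq_len(ncol(splits))) {
    ia <- splits[, k]
    u <- u_stat(pooled[ia], pooled[-ia])
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-12) extreme <- extreme + 1
  }
  extreme / ncol(splits)
}

# profile-likelihood-ratio oracle for a single-gene two-group NB test,
# maximised by grid search over (log-mean, log-dispersion)
oracle_nb_lr_p <- function(ya, yb) {
  loglik <- function(y, mu, disp) sum(stats::dnbinom(y, size = 1 / disp,
                                                     mu = mu, log = TRUE))
  mu_grid <- exp(seq(log(0.05), log(200), length.out = 400))
  disp_grid <- exp(seq(log(0.01), log(10), length.out = 200))
  best_alt <- -Inf; best_null <- -Inf
  for (d in disp_grid) {
    la <- vapply(mu_grid, function(m) loglik(ya, m, d), 0)
    lb <- vapply(mu_grid, function(m) loglik(yb, m, d), 0)
    l0 <- vapply(mu_grid, function(m) loglik(c(ya, yb), m, d), 0)
    best_alt <- max(best_alt, max(la) + max(lb))
    best_null <- max(best_null, max(l0))
  }
  stats::pchisq(2 * (best_alt - best_null), df = 1, lower.tail = FALSE)
}
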