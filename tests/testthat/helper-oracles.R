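# Independent oracles used to cross-check package computations. Each is
# deliberately written from a different formulation than the code it checks.

# Exact two-sided Mann-Whitney p by enumeration of the U statistic,
# computed from pairwise comparisons (not rank sums).
oracle_mw_exact <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- abs(u_stat(x, y) - mu)
  idx <- combn(length(pool), n1)
  devs <- apply(idx, 2, function(i) abs(u_stat(pool[i], pool[-i]) - mu))
  mean(devs >= obs - 1e-9)
}

# Textbook Benjamini-Hochberg step-up: sort ascending, q_(i) =
# min_{j >= i} p_(j) * m / j, return in the input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

# Two-group log-rank by explicit risk-set tabulation of O - E and V at
# each distinct event time.
oracle_logrank <- function(times, events, group) {
  g <- as.integer(as.factor(group)) - 1L
  et <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood for a single covariate.
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid-search maximizer of the Breslow partial likelihood.
oracle_cox_grid <- function(x, times, events, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x, times = times,
               events = events)
  grid[which.max(ll)]
}

# Spearman rho as Pearson correlation of mid-ranks.
oracle_spearman_midrank <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Small count_matrix builder for fixtures.
make_cm <- function(counts, timepoint = NULL, truth_mic = NULL) {
  counts <- as.matrix(counts)
  meta <- tibble::tibble(cell_id = paste0("c", seq_len(nrow(counts))))
  if (!is.null(timepoint)) meta$timepoint <- timepoint
  if (!is.null(truth_mic)) meta$truth_mic <- truth_mic
  count_matrix(counts, cell_ids = meta$cell_id,
               gene_ids = colnames(counts) %||%
                 paste0("g", seq_len(ncol(counts))),
               cell_meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

TIMEPOINTS_SC_TEST <- c("parental", "6h", "48h", "2mo", "4mo")

# Monte-Carlo standard error of a proportion.
mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
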