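#' Two-sample Wilcoxon rank-sum test with an exact tie-aware branch
#'
#' Two-sided test of location shift. When both groups have at most
#' `exact_max` observations the null distribution of the rank-sum
#' statistic is enumerated over all group assignments, which stays exact
#' in the presence of ties; otherwise the normal approximation with tie
#' correction (no continuity correction) is used. A pooled sample with a
#' single distinct value returns `p = 1` by convention.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest per-group size for the enumeration branch.
#' @return A list with `statistic` (rank sum of `x`), `p_value` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) {
    abort("both groups must be non-empty", class = "mictrack_input_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = w, p_value = 1, method = "degenerate"))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    dev <- abs(w - e_w)
    perms <- combn(n, n1, function(idx) sum(r[idx]))
    p <- mean(abs(perms - e_w) >= dev - 1e-9)
    return(list(statistic = w, p_value = p, method = "exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v_w <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v_w <= 0) return(list(statistic = w, p_value = 1, method = "normal"))
  z <- (w - e_w) / sqrt(v_w)
  list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Differential expression by rank-sum test
#'
#' Per-gene two-sided Wilcoxon rank-sum comparison of a target cell group
#' against the rest, on log-normalized values. The fold change is
#' `log2((mean_target + pseudocount) / (mean_rest + pseudocount))` of the
#' per-group means on the normalized scale, so sequencing depth does not
#' confound the ranking; the positive fractions use the raw
#' `value > 0` convention.
#'
#' @param norm A `normalized_matrix` from [normalize_counts()].
#' @param target_mask Logical per cell; both groups must be non-empty.
#' @param pseudocount Added to both means before the ratio (default 1e-9).
#' @return A tibble (one row per gene): `gene`, `statistic`, `p_value`,
#'   `q_value` (Benjamini-Hochberg), `log2_fc`, `pct_in`, `pct_out`.
#' @export
rank_sum_de <- function(norm, target_mask, pseudocount = 1e-9) {
  stopifnot(inherits(norm, "normalized_matrix"))
  target_mask <- as.logical(target_mask)
  if (length(target_mask) != nrow(norm$values)) {
    abort("target_mask must have one entry per cell",
          class = "mictrack_input_error")
  }
  if (!any(target_mask) || all(target_mask)) {
    abort("both target and rest groups must be non-empty",
          class = "mictrack_input_error")
  }
  vals <- as.matrix(norm$values)
  res <- purrr::map(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    a <- v[target_mask]; b <- v[!target_mask]
    ts <- rank_sum_test(a, b)
    tibble::tibble(
      gene = norm$gene_ids[j], statistic = ts$statistic,
      p_value = ts$p_value,
      log2_fc = log2((mean(a) + pseudocount) / (mean(b) + pseudocount)),
      pct_in = mean(a > 0), pct_out = mean(b > 0))
  })
  out <- dplyr::bind_rows(res)
  dplyr::mutate(out, q_value = bh_adjust(.data$p_value),
                .after = "p_value")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return FDR-adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "mictrack_input_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Select a ranked gene signature from a DE table
#'
#' Keeps genes with raw `p_value < p_cutoff`, `log2_fc > lfc_cutoff`
#' (both strict, matching the "p < 0.05, log2 fold-change > 1"
#' convention) and `pct_in >= min_pct_in`, ranks them by descending
#' fold change with ties broken by smaller p then lexicographic gene id,
#' and truncates to `max_genes`.
#'
#' @param de A tibble as returned by [rank_sum_de()].
#' @param max_genes Maximum signature size (default 100).
#' @param p_cutoff Raw p-value cutoff in (0, 1].
#' @param lfc_cutoff log2 fold-change cutoff.
#' @param min_pct_in Minimum positive fraction inside the target group.
#' @return The filtered, ranked DE tibble (possibly zero rows).
#' @export
select_signature <- function(de, max_genes = 100L, p_cutoff = 0.05,
                             lfc_cutoff = 1, min_pct_in = 0) {
  if (p_cutoff <= 0 || p_cutoff > 1) stop_config("p_cutoff", "must be in (0, 1]")
  check_fraction(min_pct_in, "min_pct_in")
  if (max_genes < 1) stop_config("max_genes", "must be >= 1")
  de |>
    dplyr::filter(.data$p_value < p_cutoff, .data$log2_fc > lfc_cutoff,
                  .data$pct_in >= min_pct_in) |>
    dplyr::arrange(dplyr::desc(.data$log2_fc), .data$p_value, .data$gene) |>
    head(max_genes)
}

#' Marker positivity fraction per timepoint
#'
#' Fraction of cells with `count > 0` for one gene at each timepoint,
#' optionally restricted to a cell mask (e.g. the planted MIC
#' subpopulation). Timepoints with no (masked) cells get an `NA`
#' fraction, distinct from an observed zero.
#'
#' @param matrix A [count_matrix()] whose `cell_meta` has a `timepoint`
#'   column.
#' @param gene A gene id present in the matrix.
#' @param group_mask Optional logical per cell.
#' @return A tibble: `timepoint`, `n_cells`, `n_positive`, `fraction`.
#' @export
positive_fraction_by_timepoint <- function(matrix, gene, group_mask = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!gene %in% matrix$gene_ids) {
    abort(paste0("unknown gene: ", gene), class = "mictrack_input_error")
  }
  if (!"timepoint" %in% names(matrix$cell_meta)) {
    abort("cell_meta lacks a timepoint column", class = "mictrack_input_error")
  }
  pos <- as.vector(matrix$counts[, gene] > 0)
  keep <- group_mask %||% rep(TRUE, length(pos))
  tp <- matrix$cell_meta$timepoint
  tp <- if (is.factor(tp)) tp else factor(tp, levels = unique(tp))
  subpopulation_trajectory(pos[keep], tp[keep]) |>
    dplyr::mutate(gene = gene, .before = 1)
}
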