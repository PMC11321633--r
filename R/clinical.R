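#' All-markers co-expression score
#'
#' Fraction of cells positive for every marker in `subset`
#' simultaneously. A singleton subset reduces to the single-marker
#' positive fraction.
#'
#' @param per_cell_flags Data frame or logical matrix, cells x markers.
#' @param subset Non-empty character vector of marker (column) names.
#' @return A fraction in `[0, 1]`.
#' @export
coexpression_score <- function(per_cell_flags, subset) {
  flags <- as.matrix(as.data.frame(per_cell_flags))
  if (!length(subset)) abort("subset must be non-empty",
                             class = "mictrack_input_error")
  missing <- setdiff(subset, colnames(flags))
  if (length(missing)) {
    abort(paste0("unknown markers: ", paste(missing, collapse = ", ")),
          class = "mictrack_input_error")
  }
  mean(rowSums(!flags[, subset, drop = FALSE]) == 0)
}

#' Differential signature score (dMISs)
#'
#' The lymph-node-metastasis co-expression score minus the paired
#' primary-tumor score: `dmiss = lnm_score - pt_score`. Antisymmetric in
#' its arguments and bounded in `[-1, 1]`. Patients scoring higher have
#' relatively more signature-co-expressing tumor cells in the metastatic
#' node than in the primary.
#'
#' @param pt_score,lnm_score Scores in `[0, 1]` (vectorized).
#' @return `lnm_score - pt_score`.
#' @export
compute_dmiss <- function(pt_score, lnm_score) {
  check_fraction(pt_score, "pt_score")
  check_fraction(lnm_score, "lnm_score")
  lnm_score - pt_score
}

#' Add co-expression scores and dMISs to a cohort table
#'
#' Uses the observed `pt_coexpr_frac` / `lnm_coexpr_frac` columns when
#' present; otherwise reconstructs each core's all-marker co-expression
#' score as the product of its per-marker positivity fractions (an
#' explicit per-cell independence assumption).
#'
#' @param cohort Cohort tibble in the `pt_<marker>_frac` /
#'   `lnm_<marker>_frac` schema.
#' @param markers Marker names (default the 4-marker mIHC panel).
#' @return The cohort with `pt_coexpr_frac`, `lnm_coexpr_frac` and
#'   `dmiss` columns filled.
#' @export
cohort_dmiss <- function(cohort,
                         markers = c("CD44", "S100A14", "RHOD", "TACSTD2")) {
  cohort <- tibble::as_tibble(cohort)
  for (side in c("pt", "lnm")) {
    col <- paste0(side, "_coexpr_frac")
    if (!col %in% names(cohort) || anyNA(cohort[[col]])) {
      cols <- paste0(side, "_", markers, "_frac")
      missing <- setdiff(cols, names(cohort))
      if (length(missing)) {
        abort(paste0("cohort lacks columns: ", paste(missing, collapse = ", ")),
              class = "mictrack_input_error")
      }
      cohort[[col]] <- apply(as.matrix(cohort[cols]), 1, prod)
    }
  }
  dplyr::mutate(cohort, dmiss = compute_dmiss(.data$pt_coexpr_frac,
                                              .data$lnm_coexpr_frac))
}

check_survival <- function(times, events) {
  if (any(times <= 0)) abort("survival times must be positive",
                             class = "mictrack_input_error")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1",
                                       class = "mictrack_input_error")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate as a step function: one row per distinct
#' observed time with the number at risk, events, and survival just after
#' that time. `S(0) = 1`; the curve drops only at event times.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A tibble: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_curve <- function(times, events) {
  check_survival(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param group Two-level group labels; both groups must be non-empty.
#' @return A list with `chi_square` and `p_value` (1 df).
#' @export
logrank_test <- function(times, events, group) {
  check_survival(times, events)
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2) {
    abort("log-rank test needs exactly two non-empty groups",
          class = "mictrack_input_error")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chi_square = unname(sd$chisq),
       p_value = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)))
}

#' Survival-based cutpoint by maximally selected log-rank statistic
#'
#' Scans candidate cutoffs — midpoints between consecutive distinct score
#' values — whose induced low (`score <= cutoff`) and high groups each
#' contain at least `minprop` of the cohort, and returns the cutoff
#' maximizing the two-group log-rank chi-square. Ties go to the smaller
#' cutoff. The p-value at a selected cutpoint is anti-conservative
#' (selection is not corrected for); `permute_p` permutation replicates
#' of the maximal statistic give an adjusted p if requested.
#'
#' @param scores Numeric per-patient scores (>= 2 distinct values).
#' @param times,events Survival data aligned with `scores`.
#' @param minprop Minimum group proportion, in (0, 0.5).
#' @param permute_p Number of permutations for a selection-adjusted p
#'   (0 = skip).
#' @return An object of class `cutpoint_result`: `cutoff`, `statistic`,
#'   `p_value` (unadjusted), `p_adjusted` (if permuted), `n_low`,
#'   `n_high`, `group` (factor low/high per patient), and the scan table.
#' @export
find_cutpoint <- function(scores, times, events, minprop = 0.1,
                          permute_p = 0) {
  check_survival(times, events)
  if (minprop <= 0 || minprop >= 0.5) stop_config("minprop", "must be in (0, 0.5)")
  n <- length(scores)
  su <- sort(unique(scores))
  if (length(su) < 2) abort("need at least 2 distinct scores",
                            class = "mictrack_input_error")
  candidates <- (su[-1] + su[-length(su)]) / 2
  scan <- max_logrank_scan(scores, times, events, candidates, minprop)
  if (!nrow(scan)) abort("no candidate cutoff satisfies minprop",
                         class = "mictrack_input_error")
  best <- scan[which.max(scan$chi_square), ]  # which.max: first (smallest) max
  group <- factor(ifelse(scores <= best$cutoff, "low", "high"),
                  levels = c("low", "high"))
  p_adj <- NA_real_
  if (permute_p > 0) {
    max_obs <- best$chi_square
    exceed <- vapply(seq_len(permute_p), function(i) {
      perm <- sample(n)
      sc <- max_logrank_scan(scores[perm], times, events, candidates, minprop)
      nrow(sc) > 0 && max(sc$chi_square) >= max_obs
    }, logical(1))
    p_adj <- mean(exceed)
  }
  structure(list(cutoff = best$cutoff, statistic = best$chi_square,
                 p_value = unname(pchisq(best$chi_square, 1, lower.tail = FALSE)),
                 p_adjusted = p_adj,
                 n_low = sum(group == "low"), n_high = sum(group == "high"),
                 group = group, scan = scan, minprop = minprop),
            class = "cutpoint_result")
}

max_logrank_scan <- function(scores, times, events, candidates, minprop) {
  n <- length(scores)
  rows <- purrr::map(candidates, function(cut) {
    low <- scores <= cut
    n_low <- sum(low)
    if (min(n_low, n - n_low) < minprop * n) return(NULL)
    lr <- logrank_test(times, events, low)
    tibble::tibble(cutoff = cut, n_low = n_low, n_high = n - n_low,
                   chi_square = lr$chi_square)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> cutoff <= %.5f (low n=%d, high n=%d)\n",
              x$cutoff, x$n_low, x$n_high))
  cat(sprintf("  log-rank chi-square %.3f, unadjusted p %.4g\n",
              x$statistic, x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf("  permutation-adjusted p %.4g\n",
                                        x$p_adjusted))
  invisible(x)
}

#' @rdname find_cutpoint
#' @param x A `cutpoint_result`.
#' @param ... Unused.
#' @export
tidy.cutpoint_result <- function(x, ...) x$scan

#' @rdname find_cutpoint
#' @export
glance.cutpoint_result <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, statistic = x$statistic,
                 p_value = x$p_value, p_adjusted = x$p_adjusted,
                 n_low = x$n_low, n_high = x$n_high, minprop = x$minprop)
}

#' Univariate Cox proportional-hazards fit
#'
#' Single-covariate partial-likelihood fit (Breslow tie handling). A
#' constant covariate returns `beta = 0` with `p = 1` (the score is
#' identically zero).
#'
#' @param x Numeric covariate.
#' @param times,events Survival data.
#' @return A list: `beta`, `hazard_ratio` (`exp(beta)`), `se`, `p_value`.
#' @export
cox_univariate <- function(x, times, events) {
  check_survival(times, events)
  if (sum(events) == 0) abort("no events: Cox model is undefined",
                              class = "mictrack_input_error")
  if (length(unique(x)) == 1L) {
    return(list(beta = 0, hazard_ratio = 1, se = NA_real_, p_value = 1))
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ x,
                         ties = "breslow")
  if (anyNA(fit$coefficients)) {
    abort(sprintf("Cox fit did not converge after %d iterations", fit$iter),
          class = "mictrack_fit_error")
  }
  s <- summary(fit)
  list(beta = unname(fit$coefficients), hazard_ratio = unname(exp(fit$coefficients)),
       se = unname(sqrt(fit$var[1, 1])), p_value = unname(s$coefficients[1, 5]))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; p-value from [stats::cor.test()]
#' (exact where available, asymptotic otherwise). Invariant under
#' strictly monotone transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A list with `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length vectors with n >= 3",
          class = "mictrack_input_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value))
}

#' Rank-based group difference tests
#'
#' Two groups: two-sided Mann-Whitney/Wilcoxon rank-sum (exact
#' enumeration when both groups have at most 8 observations, tie-aware;
#' normal approximation with tie correction otherwise). Three or more
#' groups: Kruskal-Wallis H.
#'
#' @param values Numeric outcome.
#' @param groups Categorical group labels (no empty groups).
#' @return A list: `test` ("mann-whitney" or "kruskal-wallis"),
#'   `statistic`, `p_value`, `n_groups`.
#' @export
group_difference_tests <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  if (length(values) != length(g)) {
    abort("values and groups must align", class = "mictrack_input_error")
  }
  if (any(table(g) == 0) || nlevels(g) < 2) {
    abort("need at least two non-empty groups", class = "mictrack_input_error")
  }
  if (nlevels(g) == 2) {
    lv <- levels(g)
    ts <- rank_sum_test(values[g == lv[1]], values[g == lv[2]])
    list(test = "mann-whitney", statistic = ts$statistic,
         p_value = ts$p_value, n_groups = 2L)
  } else {
    kw <- kruskal.test(values, g)
    list(test = "kruskal-wallis", statistic = unname(kw$statistic),
         p_value = unname(kw$p.value), n_groups = nlevels(g))
  }
}

#' Outcome-association battery for a scored cohort
#'
#' Runs the four standard associations of the dMISs analysis on a cohort
#' with a `dmiss` column: Cox regression of overall survival on dMISs
#' (continuous), Spearman correlation with the positive lymph-node
#' ratio, Kruskal-Wallis across tumor grades, and Mann-Whitney between
#' carcinothrombosis groups.
#'
#' @param cohort Tibble with `dmiss`, `survival_months`, `event`,
#'   `ln_ratio`, `grade`, `thrombosis`.
#' @return A tibble: `outcome`, `test`, `estimate`, `statistic`,
#'   `p_value`.
#' @export
associate_outcomes <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  cox <- cox_univariate(cohort$dmiss, cohort$survival_months, cohort$event)
  sp <- rank_correlation(cohort$dmiss, cohort$ln_ratio)
  kw <- group_difference_tests(cohort$dmiss, cohort$grade)
  mw <- group_difference_tests(cohort$dmiss, cohort$thrombosis)
  tibble::tribble(
    ~outcome, ~test, ~estimate, ~statistic, ~p_value,
    "overall_survival", "cox", cox$hazard_ratio, cox$beta, cox$p_value,
    "ln_ratio", "spearman", sp$rho, sp$rho, sp$p_value,
    "grade", kw$test, NA_real_, kw$statistic, kw$p_value,
    "thrombosis", mw$test, NA_real_, mw$statistic, mw$p_value)
}
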