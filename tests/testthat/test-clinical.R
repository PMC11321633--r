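test_that("coexpression_score counts all-marker-positive cells", {
  flags <- cbind(CD44 = c(rep(TRUE, 5), rep(FALSE, 5)),
                 S100A14 = c(rep(TRUE, 4), rep(FALSE, 6)),
                 RHOD = c(rep(TRUE, 3), rep(FALSE, 7)),
                 TACSTD2 = rep(c(TRUE, FALSE), 5))
  expect_equal(coexpression_score(flags, colnames(flags)), 0.2)
  expect_equal(coexpression_score(flags, "TACSTD2"), 0.5)
  expect_error(coexpression_score(flags, "XYZ"), "unknown markers")
  expect_error(coexpression_score(flags, character()), "non-empty")
  set.seed(6)
  rnd <- base::matrix(runif(20 * 4) < 0.5, 20, 4,
                      dimnames = list(NULL, colnames(flags)))
  brute <- mean(apply(rnd[, c("S100A14", "TACSTD2")], 1, all))
  expect_equal(coexpression_score(rnd, c("S100A14", "TACSTD2")), brute)
})

test_that("dMISs is the LNM - PT difference, antisymmetric and bounded", {
  expect_equal(compute_dmiss(0.50, 0.12), -0.38)
  expect_equal(compute_dmiss(0.3, 0.3), 0)
  expect_equal(compute_dmiss(0, 0.3996), 0.3996)
  expect_error(compute_dmiss(-0.1, 0.5), "pt_score")
  set.seed(44)
  a <- runif(100); b <- runif(100)
  d <- compute_dmiss(a, b)
  expect_equal(d, -compute_dmiss(b, a))
  expect_true(all(d >= -1 & d <= 1))
})

test_that("cohort_dmiss uses observed co-expression or the product fallback", {
  co <- generate_cohort(cohort_config(n_patients = 20, seed = 3))
  scored <- cohort_dmiss(co)
  expect_equal(scored$dmiss, co$lnm_coexpr_frac - co$pt_coexpr_frac)
  bare <- dplyr::select(co, -dplyr::any_of(c("pt_coexpr_frac",
                                             "lnm_coexpr_frac", "dmiss")))
  rebuilt <- cohort_dmiss(bare)
  pt_prod <- apply(as.matrix(bare[paste0("pt_", c("CD44", "S100A14", "RHOD",
                                                  "TACSTD2"), "_frac")]), 1, prod)
  expect_equal(rebuilt$pt_coexpr_frac, pt_prod)
  expect_error(cohort_dmiss(bare[, 1:3]), "lacks columns")
})

test_that("km_curve reproduces hand-computed product limits", {
  k1 <- km_curve(c(1, 2), c(1, 1))
  expect_equal(k1$survival, c(0.5, 0))
  k2 <- km_curve(c(1, 2), c(1, 0))
  expect_equal(k2$survival, c(0.5, 0.5))
  k3 <- km_curve(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(k3$survival == 1))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "positive")
})

test_that("log-rank is null on identical groups, symmetric, and matches the oracle", {
  t0 <- c(1, 2, 3, 1, 2, 3); e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("a", "b"), each = 3)
  null_lr <- logrank_test(t0, e0, g0)
  expect_equal(null_lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(null_lr$p_value, 1)
  tt <- c(1, 2, 3, 4, 5, 6); ee <- rep(1, 6); gg <- c(1, 1, 1, 0, 0, 0)
  expect_equal(logrank_test(tt, ee, gg)$chi_square,
               logrank_test(tt, ee, 1 - gg)$chi_square, tolerance = 1e-12)
  orc <- oracle_logrank(tt, ee, gg)
  got <- logrank_test(tt, ee, gg)
  expect_equal(got$chi_square, orc$chi_square, tolerance = 1e-4)
  expect_equal(got$p_value, orc$p_value, tolerance = 1e-4)
  set.seed(10)
  for (rep in 1:5) {
    t <- rexp(30) + 0.1; e <- rbinom(30, 1, 0.8); g <- rbinom(30, 1, 0.5)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    expect_equal(logrank_test(t, e, g)$chi_square,
                 oracle_logrank(t, e, g)$chi_square, tolerance = 1e-6)
  }
  expect_error(logrank_test(tt, ee, rep(1, 6)), "two non-empty groups")
})

test_that("find_cutpoint lands in the only admissible gap and matches brute force", {
  scores <- rep(c(0.1, 0.9), each = 10)
  times <- c(rexp(10, 1) + 0.1, rexp(10, 0.1) + 0.1)
  events <- rep(1, 20)
  cp <- find_cutpoint(scores, times, events)
  expect_gt(cp$cutoff, 0.1); expect_lt(cp$cutoff, 0.9)
  expect_equal(cp$n_low + cp$n_high, 20)
  set.seed(20)
  for (rep in 1:5) {
    n <- 30
    sc <- round(runif(n), 2)
    t <- rexp(n, exp(sc)) + 0.01
    e <- rbinom(n, 1, 0.9)
    if (sum(e) == 0 || length(unique(sc)) < 2) next
    cp <- find_cutpoint(sc, t, e, minprop = 0.1)
    su <- sort(unique(sc))
    cand <- (su[-1] + su[-length(su)]) / 2
    stats <- vapply(cand, function(cut) {
      low <- sc <= cut
      if (min(sum(low), n - sum(low)) < 0.1 * n) return(NA_real_)
      oracle_logrank(t, e, low)$chi_square
    }, numeric(1))
    best <- cand[which.max(stats)]
    expect_equal(cp$cutoff, best, tolerance = 1e-9)
    expect_equal(cp$statistic, max(stats, na.rm = TRUE), tolerance = 1e-6)
  }
  expect_error(find_cutpoint(rep(1, 10), rexp(10) + 1, rep(1, 10)),
               "distinct")
  expect_error(find_cutpoint(c(0, 1), c(1, 2), c(1, 1), minprop = 0.6),
               "minprop")
})

test_that("tidy/glance expose the cutpoint scan and summary", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 5))
  cp <- find_cutpoint(co$dmiss, co$survival_months, co$event)
  expect_s3_class(tidy(cp), "tbl_df")
  expect_true(all(c("cutoff", "chi_square") %in% names(tidy(cp))))
  gl <- glance(cp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_low + gl$n_high, 80)
  expect_s3_class(autoplot(cp), "ggplot")
})

test_that("univariate Cox obeys its symmetries and matches the grid oracle", {
  expect_equal(cox_univariate(rep(2, 10), rexp(10) + 0.1, rep(1, 10))$beta, 0)
  set.seed(30)
  x <- rnorm(8)
  t <- rexp(8, exp(0.8 * x)) + 0.05
  e <- rep(1, 8)
  fit <- cox_univariate(x, t, e)
  neg <- cox_univariate(-x, t, e)
  expect_equal(fit$beta, -neg$beta, tolerance = 1e-8)
  expect_equal(fit$hazard_ratio, exp(fit$beta))
  expect_equal(fit$beta, oracle_cox_grid(x, t, e), tolerance = 1e-3)
  expect_error(cox_univariate(x, t, rep(0, 8)), "no events")
})

test_that("Spearman correlation is monotone-invariant and tie-correct", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_equal(rank_correlation(x, exp(x))$rho, 1)  # strictly monotone map
  tied_x <- c(1, 2, 2, 3, 4, 4, 5)
  tied_y <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(rank_correlation(tied_x, tied_y)$rho,
               oracle_spearman_midrank(tied_x, tied_y), tolerance = 1e-12)
  expect_error(rank_correlation(1:2, 1:2), "n >= 3")
})

test_that("group difference tests pick the right procedure and p-values", {
  ident <- group_difference_tests(c(1, 2, 3, 1, 2, 3),
                                  rep(c("a", "b"), each = 3))
  expect_equal(ident$test, "mann-whitney")
  expect_equal(ident$p_value, 1)
  sep <- group_difference_tests(c(5, 6, 7, 1, 2, 3),
                                rep(c("hi", "lo"), each = 3))
  expect_equal(sep$p_value, 0.1)  # exact enumeration
  set.seed(9)
  vals <- c(rnorm(8), rnorm(8), rnorm(8) + 10)
  kw <- group_difference_tests(vals, rep(1:3, each = 8))
  expect_equal(kw$test, "kruskal-wallis")
  expect_gt(kw$statistic, qchisq(0.95, 1))
  expect_lt(kw$p_value, 0.05)
  expect_error(group_difference_tests(1:3, c("a", "a", "a")), "two non-empty")
})

test_that("outcome associations recover the planted links in a large cohort", {
  co <- generate_cohort(cohort_config(n_patients = 300, seed = 7))
  assoc <- associate_outcomes(co)
  expect_equal(assoc$outcome,
               c("overall_survival", "ln_ratio", "grade", "thrombosis"))
  expect_gt(assoc$estimate[assoc$outcome == "overall_survival"], 1)  # worse OS
  expect_gt(assoc$estimate[assoc$outcome == "ln_ratio"], 0)
  expect_true(all(assoc$p_value < 0.05))
})
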