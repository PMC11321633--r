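small_sc <- function(seed = 1, n = 600L, fracs = c(0.145, 0.551, 0.60, 0.70, 0.841),
                     n_genes = 15L, ...) {
  tps <- c("parental", "6h", "48h", "2mo", "4mo")
  sc_config(n_cells_per_timepoint = setNames(rep(n, 5), tps),
            mic_fraction = setNames(fracs, tps), n_genes = n_genes,
            seed = seed, ...)
}

test_that("config validation names the offending field", {
  expect_error(small_sc(fracs = c(0.1, 0.2, 0.3, 0.4, 1.2)), "mic_fraction")
  expect_error(sc_config(n_genes = 5), "n_genes")
  expect_error(small_sc(dropout_zero_prob_mic = 1.3), "dropout_zero_prob_mic")
  expect_error(small_sc(mic_fold_change = 0.5), "mic_fold_change")
  expect_error(sc_config(n_cells_per_timepoint = c(parental = -5)),
               "n_cells_per_timepoint")
})

test_that("planted MIC prevalence tracks the configured fractions", {
  cfg <- small_sc(seed = 11, n = 4000L)
  ds <- generate_sc_dataset(cfg)
  meta <- ds$matrix$cell_meta
  n_par <- sum(meta$timepoint == "parental" & meta$truth_mic)
  # anchor: 14.5% of 4000 parental cells, binomial tolerance
  expect_lt(abs(n_par - 580), 4 * sqrt(4000 * 0.145 * 0.855))
  for (tp in levels(meta$timepoint)) {
    frac <- mean(meta$truth_mic[meta$timepoint == tp])
    target <- cfg$mic_fraction[[tp]]
    expect_lt(abs(frac - target), 4 * mc_se(target, 4000))
  }
})

test_that("zero and one are honoured as degenerate MIC fractions", {
  ds <- generate_sc_dataset(small_sc(fracs = c(0, 0.5, 0.5, 0.5, 1), n = 200L))
  meta <- ds$matrix$cell_meta
  expect_equal(sum(meta$truth_mic[meta$timepoint == "parental"]), 0)
  expect_true(all(meta$truth_mic[meta$timepoint == "4mo"]))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_sc_dataset(small_sc(seed = 5, n = 150L))
  b <- generate_sc_dataset(small_sc(seed = 5, n = 150L))
  c <- generate_sc_dataset(small_sc(seed = 6, n = 150L))
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$matrix$cell_meta, b$matrix$cell_meta)
  expect_false(identical(as.matrix(a$matrix$counts), as.matrix(c$matrix$counts)))
})

test_that("MIS-gene dropout hits its configured zero probabilities", {
  cfg <- small_sc(seed = 21, n = 2500L, fracs = rep(0.4, 5))
  ds <- generate_sc_dataset(cfg)
  mic <- ds$matrix$cell_meta$truth_mic
  for (g in cfg$mis_genes) {
    col <- as.vector(ds$matrix$counts[, g])
    z_mic <- mean(col[mic] == 0)
    z_non <- mean(col[!mic] == 0)
    expect_lt(abs(z_mic - 0.2), 4 * mc_se(0.2, sum(mic)))
    expect_lt(abs(z_non - 0.95), 4 * mc_se(0.95, sum(!mic)))
  }
})

test_that("analytic filter metrics match frozen closed-form values", {
  m <- expected_filter_metrics(p0_mic = 0.2, p0_nonmic = 0.9, prevalence = 0.145)
  expect_equal(m$sensitivity, (1 - 0.2^3) * (1 - 0.2^4), tolerance = 1e-12)
  expect_equal(m$sensitivity, 0.9904128, tolerance = 1e-6)
  expect_equal(1 - m$specificity, 0.0931969, tolerance = 1e-6)
  expect_equal(m$ppv, 0.6431, tolerance = 1e-3)
  # degenerate edges: no dropout in MICs / silent non-MICs
  expect_equal(expected_filter_metrics(p0_mic = 0, p0_nonmic = 0.5)$sensitivity, 1)
  one <- expected_filter_metrics(p0_mic = 0.2, p0_nonmic = 1)
  expect_equal(one$specificity, 1)
  expect_equal(one$ppv, 1)
  expect_error(expected_filter_metrics(prevalence = 0), "prevalence")
})

test_that("analytic metrics agree with a brute-force gene-level simulation", {
  set.seed(404)
  n <- 2e5; prev <- 0.145; p0m <- 0.2; p0n <- 0.9
  mic <- runif(n) < prev
  p0 <- ifelse(mic, p0m, p0n)
  a_hit <- rbinom(n, 3, 1 - p0) > 0
  b_hit <- rbinom(n, 4, 1 - p0) > 0
  pred <- a_hit & b_hit
  m <- expected_filter_metrics(p0_mic = p0m, p0_nonmic = p0n, prevalence = prev)
  expect_lt(abs(mean(pred[mic]) - m$sensitivity),
            3 * mc_se(m$sensitivity, sum(mic)))
  expect_lt(abs(mean(!pred[!mic]) - m$specificity),
            3 * mc_se(m$specificity, sum(!mic)))
  expect_lt(abs(mean(mic[pred]) - m$ppv), 3 * mc_se(m$ppv, sum(pred)))
})

test_that("cohort generator plants the survival structure it claims", {
  co <- generate_cohort(cohort_config(n_patients = 300, seed = 7))
  expect_true(all(co$survival_months > 0))
  frac_cols <- grep("_frac$", names(co), value = TRUE)
  expect_true(all(as.matrix(co[frac_cols]) >= 0 & as.matrix(co[frac_cols]) <= 1))
  expect_true(all(co$grade %in% 1:3))
  expect_true(all(co$thrombosis %in% 0:1))
  high <- co$dmiss > -0.08
  km_med <- function(t, e) {
    kc <- km_curve(t, e)
    kc$time[which(kc$survival <= 0.5)[1]]
  }
  expect_lt(km_med(co$survival_months[high], co$event[high]),
            km_med(co$survival_months[!high], co$event[!high]))
})

test_that("degenerate censoring and the null hazard behave", {
  all_cens <- generate_cohort(cohort_config(n_patients = 40, censor_rate = 1,
                                            seed = 2))
  expect_true(all(all_cens$event == 0))
  expect_error(cohort_config(n_patients = 1), "n_patients")
  # HR = 1: fixed-median-cutoff log-rank p roughly uniform across seeds
  ps <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_config(n_patients = 60, hazard_ratio_high = 1,
                                        censor_rate = 0.2, seed = s))
    logrank_test(co$survival_months, co$event,
                 co$dmiss > median(co$dmiss))$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)  # uniform mean 0.5; far from a null-rejecting pile-up
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("colony generator conserves row counts and seeds deterministically", {
  cfg <- colony_config(timepoints = "2mo", n_mice_per_timepoint = 1L,
                       n_colonies_per_mouse = c("2mo" = 5L),
                       size_distribution = tibble::tibble(
                         timepoint = "2mo", geom_mean = 10, tail_prob = 0.2),
                       seed = 3)
  tbl <- generate_colony_table(cfg)
  expect_equal(nrow(tbl), 5)
  expect_true(all(tbl$colony_size >= 1))
  expect_identical(tbl, generate_colony_table(cfg))
  expect_error(colony_config(timepoints = character()), "timepoints")
  # degenerate size law: every colony is a single cell
  deg <- generate_colony_table(colony_config(
    timepoints = "6h", n_colonies_per_mouse = c("6h" = 8L),
    size_distribution = tibble::tibble(timepoint = "6h", geom_mean = 0,
                                       tail_prob = 0), seed = 1))
  expect_true(all(deg$colony_size == 1))
  expect_true(all(classify_colony_size(deg$colony_size) == "single"))
  full <- generate_colony_table(colony_config(seed = 9))
  expect_equal(nrow(full), sum(4L * c(60L, 80L, 40L, 12L, 10L, 6L, 5L)))
})
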