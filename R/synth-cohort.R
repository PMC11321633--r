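#' Configuration for the synthetic paired PT/LNM patient cohort
#'
#' Emulates a tissue-microarray cohort of patients with a primary tumor
#' (PT) core and a paired lymph-node metastasis (LNM) core, each scored
#' for four marker positivity fractions. The all-4-marker co-expression
#' fraction of each core is the product of its per-marker fractions
#' (per-cell independence within a core), the differential signature
#' score is dMISs = LNM co-expression - PT co-expression, and survival is
#' exponential with a piecewise hazard: `baseline_hazard` below the
#' planted cutoff and `baseline_hazard * hazard_ratio_high` above it.
#' Lymph-node ratio, tumor grade and carcinothrombosis are linked to
#' dMISs through noisy monotone links so all four outcome associations
#' are recoverable at realistic effect sizes.
#'
#' @param n_patients Number of patients (default 52, the paired-cohort
#'   size the design emulates); at least 2.
#' @param marker_names Four marker identifiers (default CD44, S100A14,
#'   RHOD, TACSTD2).
#' @param positivity_beta_params Named list with elements `pt` and `lnm`,
#'   each `c(shape1, shape2)` of the per-marker Beta law.
#' @param planted_cutoff dMISs value above which the hazard is elevated
#'   (default -0.08).
#' @param hazard_ratio_high Hazard multiplier above the cutoff (default 3).
#' @param baseline_hazard Events per month below the cutoff (default
#'   0.02, i.e. median survival near 35 months).
#' @param censor_rate Probability a patient is censored (at a uniform
#'   time before the event), in `[0, 1]`.
#' @param ln_ratio_link_slope Slope linking dMISs to the positive
#'   lymph-node ratio.
#' @param thrombosis_logit_slope,thrombosis_logit_intercept Logistic link
#'   for the carcinothrombosis flag.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 52L,
                          marker_names = c("CD44", "S100A14", "RHOD", "TACSTD2"),
                          positivity_beta_params = list(pt = c(9, 3),
                                                        lnm = c(10, 3)),
                          planted_cutoff = -0.08,
                          hazard_ratio_high = 3,
                          baseline_hazard = 0.02,
                          censor_rate = 0.2,
                          ln_ratio_link_slope = 0.8,
                          thrombosis_logit_slope = 6,
                          thrombosis_logit_intercept = -1.5,
                          seed = 1L) {
  if (n_patients < 2) stop_config("n_patients", "must be >= 2")
  if (length(marker_names) != 4) stop_config("marker_names", "must name 4 markers")
  check_positive(unlist(positivity_beta_params), "positivity_beta_params")
  check_positive(hazard_ratio_high, "hazard_ratio_high")
  check_positive(baseline_hazard, "baseline_hazard")
  check_fraction(censor_rate, "censor_rate")
  structure(list(n_patients = as.integer(n_patients),
                 marker_names = marker_names,
                 positivity_beta_params = positivity_beta_params,
                 planted_cutoff = planted_cutoff,
                 hazard_ratio_high = hazard_ratio_high,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 ln_ratio_link_slope = ln_ratio_link_slope,
                 thrombosis_logit_slope = thrombosis_logit_slope,
                 thrombosis_logit_intercept = thrombosis_logit_intercept,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic paired PT/LNM cohort
#'
#' One row per patient, following the cohort CSV schema: `patient_id`,
#' `pt_<marker>_frac` / `lnm_<marker>_frac` per-marker positivity
#' fractions, observed co-expression fractions `pt_coexpr_frac` /
#' `lnm_coexpr_frac`, `dmiss`, `survival_months`, `event`, `ln_ratio`,
#' `grade` and `thrombosis`.
#'
#' @param config A [cohort_config()].
#' @return A tibble of patient records.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  mk <- config$marker_names
  fracs <- with_substream(config$seed, "markers", {
    pt <- vapply(mk, function(m) rbeta(n, config$positivity_beta_params$pt[1],
                                       config$positivity_beta_params$pt[2]),
                 numeric(n))
    lnm <- vapply(mk, function(m) rbeta(n, config$positivity_beta_params$lnm[1],
                                        config$positivity_beta_params$lnm[2]),
                  numeric(n))
    list(pt = base::matrix(pt, nrow = n), lnm = base::matrix(lnm, nrow = n))
  })
  pt_coexpr <- apply(fracs$pt, 1, prod)
  lnm_coexpr <- apply(fracs$lnm, 1, prod)
  dmiss <- compute_dmiss(pt_coexpr, lnm_coexpr)
  high <- dmiss > config$planted_cutoff
  hazard <- config$baseline_hazard *
    ifelse(high, config$hazard_ratio_high, 1)
  surv <- with_substream(config$seed, "survival", {
    t_event <- rexp(n, rate = hazard)
    censored <- runif(n) < config$censor_rate
    time <- ifelse(censored, runif(n) * t_event, t_event)
    list(time = pmax(time, 1e-6), event = as.integer(!censored))
  })
  outcomes <- with_substream(config$seed, "outcomes", {
    ln_ratio <- pmin(1, pmax(0, 0.2 + config$ln_ratio_link_slope * dmiss +
                               rnorm(n, 0, 0.08)))
    latent <- dmiss + rnorm(n, 0, 0.12)
    grade <- cut(latent, c(-Inf, -0.06, 0.10, Inf), labels = FALSE)
    thrombosis <- as.integer(runif(n) < plogis(
      config$thrombosis_logit_intercept + config$thrombosis_logit_slope * dmiss))
    list(ln_ratio = ln_ratio, grade = grade, thrombosis = thrombosis)
  })
  out <- tibble::tibble(patient_id = sprintf("pt_%03d", seq_len(n)))
  for (i in seq_along(mk)) out[[paste0("pt_", mk[i], "_frac")]] <- fracs$pt[, i]
  for (i in seq_along(mk)) out[[paste0("lnm_", mk[i], "_frac")]] <- fracs$lnm[, i]
  dplyr::mutate(out,
                pt_coexpr_frac = pt_coexpr, lnm_coexpr_frac = lnm_coexpr,
                dmiss = dmiss,
                survival_months = surv$time, event = surv$event,
                ln_ratio = outcomes$ln_ratio, grade = outcomes$grade,
                thrombosis = outcomes$thrombosis)
}
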