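#' Configuration for synthetic lung colony-count tables
#'
#' Emulates per-mouse colony-size observations on lung sections across
#' the seven collection timepoints (2 h to 4 months). Colony sizes follow
#' a geometric law with a heavy tail: with probability `tail_prob` a
#' colony is a large, nodule-scale lesion (200 plus a geometric excess),
#' otherwise `1 + Geometric` around `geom_mean`. The defaults sketch the
#' observed dynamics — initial seeding as single cells/small colonies,
#' attrition through 48 h and 1 week, medium colonies by 2 months and
#' visible nodules at 4 months.
#'
#' @param timepoints Timepoint labels (default the seven collection
#'   times).
#' @param n_mice_per_timepoint Mice per timepoint (default 4).
#' @param n_colonies_per_mouse Named integer vector, colonies observed
#'   per mouse at each timepoint.
#' @param size_distribution Tibble with columns `timepoint`, `geom_mean`
#'   (mean excess size of ordinary colonies) and `tail_prob` (probability
#'   of a nodule-scale colony).
#' @param seed Integer seed.
#' @return An object of class `colony_config`.
#' @export
colony_config <- function(timepoints = TIMEPOINTS_COLONY,
                          n_mice_per_timepoint = 4L,
                          n_colonies_per_mouse = setNames(
                            c(60L, 80L, 40L, 12L, 10L, 6L, 5L),
                            TIMEPOINTS_COLONY),
                          size_distribution = default_colony_sizes(),
                          seed = 1L) {
  if (!length(timepoints)) stop_config("timepoints", "must be non-empty")
  check_positive(n_mice_per_timepoint, "n_mice_per_timepoint")
  check_positive(n_colonies_per_mouse, "n_colonies_per_mouse")
  size_distribution <- tibble::as_tibble(size_distribution)
  if (!all(timepoints %in% size_distribution$timepoint)) {
    stop_config("size_distribution", "must cover every timepoint")
  }
  check_fraction(size_distribution$tail_prob, "size_distribution$tail_prob")
  check_positive(size_distribution$geom_mean, "size_distribution$geom_mean",
                 strict = FALSE)
  structure(list(timepoints = timepoints,
                 n_mice_per_timepoint = as.integer(n_mice_per_timepoint),
                 n_colonies_per_mouse = n_colonies_per_mouse,
                 size_distribution = size_distribution,
                 seed = as.integer(seed)),
            class = "colony_config")
}

#' Default colony-size law per timepoint
#' @return A tibble: `timepoint`, `geom_mean`, `tail_prob`.
#' @export
default_colony_sizes <- function() {
  tibble::tribble(
    ~timepoint, ~geom_mean, ~tail_prob,
    "2h",   0.5,  0.00,
    "6h",   1.0,  0.00,
    "24h",  3.0,  0.00,
    "48h",  2.0,  0.00,
    "1wk",  4.0,  0.00,
    "2mo", 40.0,  0.05,
    "4mo", 80.0,  0.40)
}

#' Generate a synthetic colony table
#'
#' One row per colony with columns `mouse_id`, `timepoint`,
#' `colony_size`. Row counts are deterministic (mice times colonies per
#' mouse at each timepoint); sizes are stochastic but seeded.
#'
#' @param config A [colony_config()].
#' @return A tibble of colonies with all sizes >= 1.
#' @export
generate_colony_table <- function(config = colony_config()) {
  stopifnot(inherits(config, "colony_config"))
  with_substream(config$seed, "colonies", {
    rows <- purrr::map(config$timepoints, function(tp) {
      law <- dplyr::filter(config$size_distribution, .data$timepoint == tp)
      per_mouse <- config$n_colonies_per_mouse[[tp]]
      purrr::map(seq_len(config$n_mice_per_timepoint), function(m) {
        k <- per_mouse
        tail <- runif(k) < law$tail_prob
        base_size <- 1L + (if (law$geom_mean > 0) {
          rgeom(k, prob = 1 / (1 + law$geom_mean))
        } else rep(0L, k))
        size <- ifelse(tail, 200L + rgeom(k, prob = 1 / 201) + 1L, base_size)
        tibble::tibble(mouse_id = sprintf("%s_mouse%d", tp, m),
                       timepoint = tp, colony_size = as.integer(size))
      }) |> dplyr::bind_rows()
    })
    dplyr::bind_rows(rows)
  })
}
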