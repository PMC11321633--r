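#' EMT state decision thresholds
#'
#' The epithelial (E) condition holds when the fraction of cells positive
#' (`count > 0`) for the epithelial marker exceeds `e_frac_min` (default
#' 0.5, strict); the mesenchymal (M) condition when the mesenchymal-marker
#' positive fraction exceeds `m_frac_min` (default 0.10, strict). Both
#' conditions together give quasi-EM. A group meeting neither condition
#' but with epithelial-marker fraction above `partial_e_floor` (default
#' 0.10, strict; a configurable convention, not a published threshold) is
#' partial-E; anything else is undetermined.
#'
#' @param e_frac_min,m_frac_min,partial_e_floor Fractions in `[0, 1]`
#'   with `partial_e_floor < e_frac_min`.
#' @return An object of class `emt_thresholds`.
#' @export
emt_thresholds <- function(e_frac_min = 0.5, m_frac_min = 0.10,
                           partial_e_floor = 0.10) {
  check_fraction(c(e_frac_min, m_frac_min, partial_e_floor), "emt thresholds")
  if (partial_e_floor >= e_frac_min) {
    stop_config("partial_e_floor", "must be below e_frac_min")
  }
  structure(list(e_frac_min = e_frac_min, m_frac_min = m_frac_min,
                 partial_e_floor = partial_e_floor),
            class = "emt_thresholds")
}

EMT_STATES <- c("E", "partial-E", "M", "quasi-EM", "undetermined")

#' Assign an EMT state from marker positivity fractions
#'
#' Vectorized total partition of the unit square into the five states
#' described in [emt_thresholds()].
#'
#' @param frac_e_positive,frac_m_positive Positive fractions in `[0, 1]`
#'   for the epithelial and mesenchymal markers.
#' @param thresholds An [emt_thresholds()].
#' @return A factor with levels E, partial-E, M, quasi-EM, undetermined.
#' @export
assign_emt_state <- function(frac_e_positive, frac_m_positive,
                             thresholds = emt_thresholds()) {
  check_fraction(frac_e_positive, "frac_e_positive", allow_na = TRUE)
  check_fraction(frac_m_positive, "frac_m_positive", allow_na = TRUE)
  e_cond <- frac_e_positive > thresholds$e_frac_min
  m_cond <- frac_m_positive > thresholds$m_frac_min
  state <- dplyr::case_when(
    is.na(frac_e_positive) | is.na(frac_m_positive) ~ "undetermined",
    e_cond & m_cond ~ "quasi-EM",
    e_cond ~ "E",
    m_cond ~ "M",
    frac_e_positive > thresholds$partial_e_floor ~ "partial-E",
    TRUE ~ "undetermined")
  factor(state, levels = EMT_STATES)
}

#' EMT state trajectory across grouped cells
#'
#' Computes, per group, the positive fractions of an epithelial and a
#' mesenchymal marker gene and assigns the EMT state. The grouping is by
#' timepoint, optionally refined by a per-cell subpopulation label so
#' that, e.g., parental MIC cells form their own group. Groups with no
#' cells are undetermined.
#'
#' @param matrix A [count_matrix()] with a `timepoint` metadata column.
#' @param e_gene,m_gene Epithelial / mesenchymal marker gene ids.
#' @param subpop Optional per-cell label combined with timepoint into the
#'   group key.
#' @param thresholds An [emt_thresholds()].
#' @return A tibble: grouping columns, `n_cells`, `frac_e`, `frac_m`,
#'   `state`.
#' @export
emt_trajectory <- function(matrix, e_gene, m_gene, subpop = NULL,
                           thresholds = emt_thresholds()) {
  stopifnot(inherits(matrix, "count_matrix"))
  missing <- setdiff(c(e_gene, m_gene), matrix$gene_ids)
  if (length(missing)) {
    abort(paste0("marker genes missing from matrix: ",
                 paste(missing, collapse = ", ")),
          class = "mictrack_input_error")
  }
  df <- tibble::tibble(
    timepoint = matrix$cell_meta$timepoint,
    e_pos = as.vector(matrix$counts[, e_gene] > 0),
    m_pos = as.vector(matrix$counts[, m_gene] > 0))
  if (!is.null(subpop)) df$subpop <- subpop
  keys <- c("timepoint", if (!is.null(subpop)) "subpop")
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .drop = FALSE) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     frac_e = ifelse(dplyr::n() > 0, mean(.data$e_pos), NA_real_),
                     frac_m = ifelse(dplyr::n() > 0, mean(.data$m_pos), NA_real_),
                     .groups = "drop")
  dplyr::mutate(out, state = assign_emt_state(.data$frac_e, .data$frac_m,
                                              thresholds))
}

#' Paper-style EMT state sequence for a simulated dataset
#'
#' Convenience wrapper reproducing the grouped view used for the
#' five-stage trajectory: parental cells split into the MIC subpopulation
#' (its own group) while each later timepoint is pooled. Returns one row
#' per stage: parental MICs, then 6 h, 48 h, 2 mo, 4 mo.
#'
#' @param dataset A `synthetic_sc_dataset` from [generate_sc_dataset()].
#' @param thresholds An [emt_thresholds()].
#' @return A tibble: `stage`, `n_cells`, `frac_e`, `frac_m`, `state`.
#' @export
emt_state_sequence <- function(dataset, thresholds = emt_thresholds()) {
  stopifnot(inherits(dataset, "synthetic_sc_dataset"))
  cm <- dataset$matrix
  e_gene <- dataset$config$emt_genes[["e"]]
  m_gene <- dataset$config$emt_genes[["m"]]
  meta <- cm$cell_meta
  parental <- meta$timepoint == "parental"
  stage <- ifelse(parental & meta$truth_mic, "parental-S",
                  ifelse(parental, "parental-other", as.character(meta$timepoint)))
  traj <- emt_trajectory(cm, e_gene, m_gene, subpop = stage,
                         thresholds = thresholds)
  keep <- c("parental-S", setdiff(levels(meta$timepoint), "parental"))
  traj |>
    dplyr::filter(.data$timepoint == .data$subpop |
                    (.data$timepoint == "parental" &
                       .data$subpop %in% c("parental-S"))) |>
    dplyr::transmute(stage = .data$subpop, n_cells = .data$n_cells,
                     frac_e = .data$frac_e, frac_m = .data$frac_m,
                     state = .data$state) |>
    dplyr::arrange(match(.data$stage, keep))
}

#' Classify a metastatic colony by size
#'
#' The four cross-sectional size classes: `single` (1 cell), `small`
#' (2-10), `medium` (11-200) and `nodule` (>200, a visible metastatic
#' nodule).
#'
#' @param size Positive integer colony sizes.
#' @return A factor with levels single, small, medium, nodule.
#' @export
classify_colony_size <- function(size) {
  if (!is.numeric(size) || any(is.na(size)) || any(size < 1) ||
      any(size != round(size))) {
    abort("colony sizes must be integers >= 1", class = "mictrack_input_error")
  }
  cut(size, breaks = c(0, 1, 10, 200, Inf),
      labels = c("single", "small", "medium", "nodule"))
}

#' Summarise a colony table by timepoint and size class
#'
#' @param table Tibble with columns `timepoint` and `colony_size` (and
#'   typically `mouse_id`), one row per colony.
#' @param area_mm2 Optional positive section area; when given, per-area
#'   rates (`count / area_mm2`) are added and the area is recorded.
#' @return A tibble: `timepoint`, `size_class`, `count`, `total` (per
#'   timepoint), and with area `area_mm2`, `rate_per_mm2`.
#' @export
summarize_colonies <- function(table, area_mm2 = NULL) {
  table <- tibble::as_tibble(table)
  if (!is.null(area_mm2)) check_positive(area_mm2, "area_mm2")
  if (!nrow(table)) {
    out <- tibble::tibble(timepoint = character(), size_class = factor(
      character(), levels = c("single", "small", "medium", "nodule")),
      count = integer(), total = integer())
    return(out)
  }
  out <- table |>
    dplyr::mutate(size_class = classify_colony_size(.data$colony_size)) |>
    dplyr::count(.data$timepoint, .data$size_class, .drop = FALSE,
                 name = "count") |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup()
  if (!is.null(area_mm2)) {
    out <- dplyr::mutate(out, area_mm2 = area_mm2,
                         rate_per_mm2 = .data$count / area_mm2)
  }
  out
}
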