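#' Simulate the full synthetic study to disk
#'
#' Generates the three study inputs — the multi-timepoint single-cell
#' count triple, the paired PT/LNM cohort and the colony table — and
#' writes them in their interchange formats under `out_dir`:
#' `sc/matrix.mtx` + `sc/barcodes.tsv` + `sc/features.tsv`,
#' `cohort.csv`, `colonies.csv`, plus a verbatim `config.yaml` echo.
#' Identical seeds give byte-identical data files.
#'
#' @param out_dir Output directory (created).
#' @param seed Top-level seed; the per-generator seeds default to it.
#' @param sc,cohort,colony Optional [sc_config()], [cohort_config()],
#'   [colony_config()] overrides.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, sc = NULL, cohort = NULL,
                         colony = NULL) {
  sc <- sc %||% sc_config(seed = seed)
  cohort <- cohort %||% cohort_config(seed = seed)
  colony <- colony %||% colony_config(seed = seed)
  dir.create(file.path(out_dir, "sc"), recursive = TRUE, showWarnings = FALSE)
  dataset <- generate_sc_dataset(sc)
  cohort_tbl <- generate_cohort(cohort)
  colony_tbl <- generate_colony_table(colony)
  write_count_matrix(dataset$matrix, file.path(out_dir, "sc"))
  readr::write_csv(cohort_tbl, file.path(out_dir, "cohort.csv"), progress = FALSE)
  readr::write_csv(colony_tbl, file.path(out_dir, "colonies.csv"), progress = FALSE)
  yaml::write_yaml(list(seed = seed,
                        sc = config_as_list(sc),
                        cohort = config_as_list(cohort),
                        colony = config_as_list(colony)),
                   file.path(out_dir, "config.yaml"))
  invisible(list(dataset = dataset, cohort = cohort_tbl, colonies = colony_tbl,
                 dir = out_dir))
}

config_as_list <- function(config) {
  lapply(unclass(config), function(x) {
    if (is.data.frame(x)) lapply(as.list(x), identity) else x
  })
}

#' Run the full analysis pipeline on a simulated dataset directory
#'
#' Reads the artifacts written by [run_simulate()] and executes the
#' downstream stages in order — differential expression and signature
#' selection, 1+1 classification and confusion-matrix evaluation
#' (parental cells, against planted truth), subpopulation and EMT
#' trajectories, colony summaries, and the clinical dMISs scoring with
#' survival cutpoint selection and outcome associations. Results are
#' written under `out_dir` with fixed schemas plus a run manifest.
#'
#' @param in_dir Directory produced by [run_simulate()].
#' @param out_dir Results directory (created).
#' @param panel A [signature_panel()].
#' @param thresholds An [emt_thresholds()].
#' @param e_gene,m_gene EMT marker gene ids.
#' @param minprop Minimum group proportion for the cutpoint search.
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_analyze <- function(in_dir, out_dir, panel = signature_panel(),
                        thresholds = emt_thresholds(),
                        e_gene = "CTNNB1", m_gene = "SNAI1", minprop = 0.1) {
  paths <- c(matrix = file.path(in_dir, "sc", "matrix.mtx"),
             cells = file.path(in_dir, "sc", "barcodes.tsv"),
             genes = file.path(in_dir, "sc", "features.tsv"),
             cohort = file.path(in_dir, "cohort.csv"),
             colonies = file.path(in_dir, "colonies.csv"))
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      abort(paste0("missing input file: ", paths[[nm]]),
            class = "mictrack_io_error")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)), parent = e)
    })
  }

  cm <- stage("matrixio", read_count_matrix(paths["matrix"], paths["cells"],
                                            paths["genes"]))
  meta <- cm$cell_meta
  parental <- meta$timepoint == "parental"

  de <- stage("designatures", {
    par_idx <- which(parental)
    par_cm <- count_matrix(cm$counts[par_idx, , drop = FALSE],
                           cell_ids = cm$cell_ids[par_idx],
                           gene_ids = cm$gene_ids,
                           cell_meta = meta[par_idx, , drop = FALSE])
    rank_sum_de(normalize_counts(par_cm), meta$truth_mic[par_idx])
  })
  sig <- select_signature(de, max_genes = 100)

  calls <- stage("micfilter", classify_cells(cm, panel))
  metrics <- stage("micfilter",
                   evaluate_classifier(calls$mic_call, meta$truth_mic,
                                       subset = parental))
  traj <- stage("micfilter",
                subpopulation_trajectory(calls$mic_call, meta$timepoint))

  emt <- stage("phenostates", {
    stageing <- ifelse(parental & meta$truth_mic, "parental-S",
                       ifelse(parental, "parental-other",
                              as.character(meta$timepoint)))
    emt_trajectory(cm, e_gene, m_gene, subpop = stageing,
                   thresholds = thresholds)
  })

  colonies <- stage("phenostates", {
    tbl <- readr::read_csv(paths["colonies"], show_col_types = FALSE,
                           progress = FALSE)
    summarize_colonies(tbl, area_mm2 = 20)
  })

  clin <- stage("clinical", {
    cohort <- readr::read_csv(paths["cohort"], show_col_types = FALSE,
                              progress = FALSE)
    scored <- cohort_dmiss(cohort)
    cp <- find_cutpoint(scored$dmiss, scored$survival_months, scored$event,
                        minprop = minprop)
    assoc <- associate_outcomes(scored)
    list(scored = scored, cutpoint = cp, associations = assoc)
  })

  readr::write_csv(de, file.path(out_dir, "de.csv"), progress = FALSE)
  readr::write_csv(sig, file.path(out_dir, "signature.csv"), progress = FALSE)
  readr::write_csv(tidy(metrics), file.path(out_dir, "metrics.csv"),
                   progress = FALSE)
  readr::write_csv(traj, file.path(out_dir, "trajectory.csv"), progress = FALSE)
  readr::write_csv(emt, file.path(out_dir, "emt.csv"), progress = FALSE)
  readr::write_csv(colonies, file.path(out_dir, "colonies_summary.csv"),
                   progress = FALSE)
  readr::write_csv(dplyr::select(clin$scored, "patient_id", "pt_coexpr_frac",
                                 "lnm_coexpr_frac", "dmiss"),
                   file.path(out_dir, "dmiss.csv"), progress = FALSE)
  jsonlite::write_json(glance(clin$cutpoint), file.path(out_dir, "cutpoint.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_csv(clin$associations, file.path(out_dir, "associations.csv"),
                   progress = FALSE)
  manifest <- list(package = "mictrack",
                   version = as.character(utils::packageVersion("mictrack")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   in_dir = normalizePath(in_dir),
                   minprop = minprop,
                   panel = unclass(panel),
                   thresholds = unclass(thresholds))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(de = de, signature = sig, metrics = metrics, trajectory = traj,
                 emt = emt, colonies = colonies, dmiss = clin$scored,
                 cutpoint = clin$cutpoint, associations = clin$associations))
}
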