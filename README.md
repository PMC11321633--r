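# mictrack

Identification and scoring of **metastasis-initiating cells (MICs)** in
multi-timepoint single-cell experiments, plus the clinical scoring that
follows from them. When tumor cells are tracked from a parental culture
through early (6 h, 48 h) and late (2, 4 months) lung-colonization
timepoints, the founding subpopulation can be recognized by a small
marker panel; `mictrack` implements that recognition machinery end to
end, with synthetic data of known ground truth so every operating
characteristic is verifiable.

## What it implements

* **The 1+1 co-expression classifier.** A cell is called a MIC when at
  least one Group A gene (C19orf33, S100A14, RHOD) *and* one Group B
  gene (CST6, CD44, TM4SF1, TACSTD2) have raw count ≥ 1. Its expected
  performance under per-gene dropout is available in closed form:
  `sens = (1 − p₀ₘ^|A|)(1 − p₀ₘ^|B|)`, FPR analogously with the non-MIC
  zero probability, PPV/NPV by Bayes at a given prevalence
  (`expected_filter_metrics()`), and empirically via `classify_cells()` +
  `evaluate_classifier()`.
* **A seeded single-cell simulator** (`generate_sc_dataset()`): negative
  binomial counts, log-normal gene means, a planted MIC subpopulation
  enriching 14.5% → 55.1% → … → 84.1% across five timepoints, with
  per-gene dropout targets hit exactly through the NB zero mass.
* **EMT state assignment** (`assign_emt_state()`, `emt_trajectory()`):
  E when >50% of cells are CTNNB1-positive, M when >10% are
  SNAI1-positive, quasi-EM when both, partial-E below the E threshold.
* **Colony-size dynamics** (`classify_colony_size()`,
  `summarize_colonies()`): single / small (2–10) / medium (11–200) /
  nodule (>200) bins over per-mouse colony tables.
* **Clinical dMISs scoring** (`cohort_dmiss()`, `find_cutpoint()`,
  `associate_outcomes()`): per-patient differential co-expression score
  (lymph-node metastasis minus paired primary tumor), survival cutpoint
  by maximally selected log-rank statistic, and Cox / Spearman /
  Kruskal–Wallis / Mann–Whitney outcome associations.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and `plot_*()`/`autoplot()` helpers.

## Worked example

```r
library(mictrack)

cfg <- sc_config(
  n_cells_per_timepoint = setNames(rep(1000L, 5),
                                   c("parental", "6h", "48h", "2mo", "4mo")),
  n_genes = 30, seed = 1)
ds <- generate_sc_dataset(cfg)

calls <- classify_cells(ds$matrix)            # the 1+1 rule, per cell
evaluate_classifier(calls$mic_call, ds$matrix$cell_meta$truth_mic,
                    subset = ds$matrix$cell_meta$timepoint == "parental")
#> <confusion_metrics>
#>   tp=149 fp=23 fn=2 tn=826 (n=1000)
#>   ppv=0.8663 npv=0.9976 sens=0.9868 spec=0.9729 acc=0.9750

expected_filter_metrics(cfg, prevalence = 0.145)
#> <confusion_metrics> (analytic)
#>   ppv=0.8639 npv=0.9983 sens=0.9904 spec=0.9735 acc=0.9760

emt_state_sequence(ds)[, c("stage", "state")]
#> # A tibble: 5 × 2
#>   stage      state
#>   <chr>      <fct>
#> 1 parental-S partial-E
#> 2 6h         M
#> 3 48h        quasi-EM
#> 4 2mo        E
#> 5 4mo        E
```

The first call evaluates the boolean filter against the planted truth on
parental cells: at 14.5% prevalence it recovers essentially all MICs
(sensitivity 0.99) at a positive predictive value near 0.87, and the
empirical numbers sit within Monte-Carlo error of the closed-form
prediction printed below them. The EMT sequence shows the plasticity
trajectory the state rule encodes: sub-threshold epithelial parental
MICs turn mesenchymal on arrival, pass through a mixed quasi-EM state
while anchoring, and return to the epithelial state during colonization.

On the clinical side:

```r
cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 7))
cut <- find_cutpoint(cohort$dmiss, cohort$survival_months, cohort$event)
cut
#> <cutpoint_result> cutoff <= -0.07751 (low n=74, high n=226)
#>   log-rank chi-square 73.861, unadjusted p 8.382e-18
```

The cohort generator plants a hazard step (ratio 3) at dMISs = −0.08;
the maximally selected log-rank scan recovers a cutoff of −0.078 and
splits the cohort into the low-score (better-prognosis) and high-score
groups.

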