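# dmngc — Granger-causal hub analysis of the default-mode network

`dmngc` is an R package for resting-state *effective* connectivity
analysis of the eight-node default-mode network (DMN: PCC, MPFC, bilateral
IPC, bilateral ITC, bilateral hippocampal formation).  It is aimed at
researchers who want to quantify directed influences between DMN nodes
from ROI BOLD time courses, summarise each subject's causal network, and
test whether hub communication separates a patient cohort from controls.

## What it computes

For every ordered pair of regions \(x, y\), a bivariate VAR(p) is fitted
(ordinary least squares, or Fast Orthogonal Search — greedy orthogonal
regressor selection) and Geweke's linear-feedback measures are computed:

- F_(x→y) = ln( σ²_restricted(y) / σ²_full(y) ) — the prediction gain from
  x's past;
- F_(y→x), symmetrically;
- F_(x·y) = ln( σ²_x σ²_y / det Σ ) — instantaneous (undirected)
  dependence, reported but never drawn as an edge.

Significance of each directed influence is judged against IAAFT
surrogates (value distribution preserved exactly, spectrum approximately;
source series surrogated, target fixed), with the add-one p-value
p = (1 + #{F_surr ≥ F_obs})/(1 + N) at a one-sided level α = 0.05 and
N = 1000 surrogates by default.

Each subject's significant influences form a directed graph over the DMN
nodes with hubs {PCC, MPFC, lIPC, rIPC}.  The hub-communication index

    D_outer / D_all

is the number of significant hub↔non-hub connections over the total
number of significant connections.  Cohorts are compared with a
one-tailed Welch test and one-way ANOVA on this index, and a ROC sweep
(patients score *low*) picks the Youden-optimal cutoff.

A synthetic-cohort generator produces stable VAR(5) cohorts with known
hub-centric causal structure (and an "attenuated" patient variant that
weakens MPFC/IPC couplings while sparing PCC afferents), so the entire
pipeline is testable end-to-end without scan data.  Temporal
preprocessing (initial-volume discard, linear detrend, 0.01–0.1 Hz ideal
band-pass, global-signal removal) and ROI utilities (mm-space sphere
masks, thresholded-map intersection, template goodness-of-fit component
selection, ROI time-series extraction) are included.

## Worked example

```r
library(dmngc)

ctrl <- make_default_coupling("control")     # ground-truth VAR(5) coupling
ts <- simulate_subject(ctrl, n_timepoints = 295, seed = 1)
ts
#> ts_matrix: 295 time points x 8 regions (TR = 2 s)
#> regions: PCC, MPFC, lIPC, rIPC, lITC, rITC, lHC, rHC

geweke_measures(ts$values[, "MPFC"], ts$values[, "lIPC"], order = 5)
#> F_x->y = 0.3770 (p not tested)
#> F_y->x = 0.0131 (p not tested)
#> F_x.y  = 0.0006 (instantaneous, not tested)

r <- test_direction(ts$values[, "MPFC"], ts$values[, "lIPC"], order = 5,
                    surrogate_config(n_surrogates = 200, seed = 7))
sprintf("MPFC -> lIPC: F = %.3f, p = %.4f", r$f_observed, r$p_value)
#> "MPFC -> lIPC: F = 0.377, p = 0.0050"
```

MPFC genuinely drives lIPC in the generating model, and the test agrees:
the observed prediction gain (F = 0.377) exceeds every one of the 200
surrogate values (p = 1/201 ≈ 0.005 < 0.05).  The reverse direction's
F = 0.013 is what no influence looks like at T = 295.

A two-cohort analysis end to end, at the cohort sizes of a typical
aging/dementia study (16 controls vs 15 patients; `n_surrogates = 200`
with curtailment for speed — a few minutes on one CPU):

```r
cfg <- run_config(
  mode = "synthetic",
  control_spec = cohort_spec(make_default_coupling("control"), 16, 295, seed = 1),
  patient_spec = cohort_spec(make_default_coupling("attenuated", 0.4), 15, 295, seed = 2),
  surrogate = surrogate_config(n_surrogates = 200, early_stop = TRUE),
  seed = 1)
run_pipeline(cfg)
#> pipeline_report: 16 control + 15 patient subjects
#> mean D_outer/D_all: control 0.7068, patient 0.6449
#> one-tailed p = 0.000759, ANOVA p = 0.0008279
#> ROC cutoff 0.6887: sensitivity 80.00%, specificity 87.50%
```

The control group's hub index sits near 16/22 ≈ 0.73 (the generating
network has 22 directed couplings, 16 of them hub↔non-hub); attenuating
the MPFC/IPC couplings pulls the patient group down, and the Youden
cutoff separates the cohorts.  In this run the 22 edges drawn in the
thickest (>80% of subjects) band are exactly the 22 ground-truth
couplings.  `run_pipeline()` also writes per-subject edge
tables, group edge-proportion tables, the hub-index table, the ROC table
and a JSON report when `out_dir` is set.  A command-line wrapper lives at
`scripts/run_pipeline.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package:

- **t1** — the specificity (in percent) of the hub-index classifier at
  the Youden-optimal ROC cutoff, on score sets consistent with the
  reference confusion counts (16 controls / 15 patients, 13 of each
  correctly categorised at cutoff 0.647);
- **t2** — the empirical false-positive rate of the IAAFT-surrogate
  Granger test over 200 independent white-noise pairs (length 295, VAR
  order 5, 200 surrogates, one-sided level 0.05).

and writes them as JSON to `--out`.

## Package layout

- `R/synthetic.R` — coupling specs, cohort simulation, ground truth
- `R/preprocess.R` — discard / detrend / band-pass / global-signal removal
- `R/granger.R`, `src/core.cpp` — VAR fitting (OLS, FOS), Geweke measures
- `R/surrogate.R` — IAAFT surrogates and significance testing
- `R/network.R` — causal graphs, D_outer/D_all, edge-proportion bands
- `R/classify.R` — Welch/ANOVA group tests, ROC, optimal cutoff
- `R/roi.R` — sphere masks, template fit score, ROI extraction
- `R/pipeline.R` — `run_config()` / `run_pipeline()` orchestration
- `vignettes/dmn-granger-hubs.Rmd` — models, assumptions, design choices
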