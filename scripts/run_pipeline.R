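#!/usr/bin/env Rscript

# Thin command-line wrapper over dmngc::run_pipeline(): simulate two
# synthetic cohorts (or load directories of TSV time series) and run the
# full effective-connectivity analysis.
#
#   Rscript scripts/run_pipeline.R --out results/run1 --seed 1
#   Rscript scripts/run_pipeline.R --control-dir data/old --patient-dir \
#       data/ad --preprocess --out results/run2 --seed 1

suppressPackageStartupMessages({
  library(optparse)
  library(dmngc)
})

opt_list <- list(
  make_option("--control-dir", type = "character", default = NULL,
              dest = "control_dir"),
  make_option("--patient-dir", type = "character", default = NULL,
              dest = "patient_dir"),
  make_option("--n-control", type = "integer", default = 16L,
              dest = "n_control"),
  make_option("--n-patient", type = "integer", default = 15L,
              dest = "n_patient"),
  make_option("--n-timepoints", type = "integer", default = 295L,
              dest = "n_timepoints"),
  make_option("--attenuation", type = "double", default = 0.4),
  make_option("--n-surrogates", type = "integer", default = 1000L,
              dest = "n_surrogates"),
  make_option("--fast", action = "store_true", default = FALSE,
              help = "200 surrogates with curtailment"),
  make_option("--alpha", type = "double", default = 0.05),
  make_option("--order", type = "integer", default = 5L),
  make_option("--discard", type = "integer", default = 5L),
  make_option("--flo", type = "double", default = 0.01),
  make_option("--fhi", type = "double", default = 0.1),
  make_option("--no-gsr", action = "store_true", default = FALSE,
              dest = "no_gsr"),
  make_option("--preprocess", action = "store_true", default = FALSE),
  make_option("--out", type = "character", default = "results/pipeline"),
  make_option("--seed", type = "integer", default = 1L))
opts <- parse_args(OptionParser(option_list = opt_list))

sur <- surrogate_config(
  n_surrogates = if (opts$fast) 200L else opts$n_surrogates,
  alpha = opts$alpha, early_stop = opts$fast)

if (is.null(opts$control_dir)) {
  cfg <- run_config(
    mode = "synthetic",
    control_spec = cohort_spec(make_default_coupling("control"),
                               opts$n_control, opts$n_timepoints,
                               seed = 1),
    patient_spec = cohort_spec(
      make_default_coupling("attenuated", opts$attenuation),
      opts$n_patient, opts$n_timepoints, seed = 2),
    preprocess = if (opts$preprocess) TRUE else NULL,
    discard = opts$discard, f_lo = opts$flo, f_hi = opts$fhi,
    gsr = !opts$no_gsr, order = opts$order, surrogate = sur,
    out_dir = opts$out, seed = opts$seed)
} else {
  cfg <- run_config(
    mode = "load", control_dir = opts$control_dir,
    patient_dir = opts$patient_dir,
    preprocess = if (opts$preprocess) TRUE else NULL,
    discard = opts$discard, f_lo = opts$flo, f_hi = opts$fhi,
    gsr = !opts$no_gsr, order = opts$order, surrogate = sur,
    out_dir = opts$out, seed = opts$seed)
}

report <- run_pipeline(cfg)
print(report)
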