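#!/usr/bin/env Rscript

# Stage 2: follow-up scheme and metabolite preprocessing.
#
# Applies the 10-year follow-up scheme (baseline exclusions, administrative
# censoring at 10 years, follow-up-dependent control criteria), then converts
# raw concentrations to standardized metabolite-to-creatinine ratios:
# half-minimum zero replacement, creatinine normalization, per-metabolite
# log/sqrt transform by skewness, standardization, and the 50% missingness
# filter used by the metabolome-wide screen.

suppressMessages(library(uricad))

cohort <- read_cohort("results/cohort")
scheme <- followup_scheme("10y")
analysis <- apply_followup_scheme(cohort, scheme)
cat(sprintf("10-year scheme: %d cases / %d controls (input %d; %d baseline-excluded, %d controls dropped by the rule)\n",
            analysis$n_cases, analysis$n_controls, analysis$n_input,
            analysis$n_excluded_baseline, analysis$n_excluded_controls))

keep <- match(analysis$data$id, cohort$clinical$id)
panel <- metabolite_panel(cohort$metabolites$values[keep, , drop = FALSE],
                          cohort$metabolites$creatinine[keep])
proc <- preprocess_panel(panel)
filt <- filter_missingness(proc, 0.5)

cat(sprintf("transforms: %d log, %d sqrt\n",
            sum(proc$transform_record == "log"),
            sum(proc$transform_record == "sqrt")))
cat(sprintf("excluded for >50%% missingness: %s\n",
            paste(filt$excluded, collapse = ", ")))

dir.create("results", showWarnings = FALSE)
write.csv(cbind(id = analysis$data$id,
                as.data.frame(filt$panel$values, check.names = FALSE)),
          "results/processed_panel.csv", row.names = FALSE)
write.csv(analysis$data, "results/analysis_cohort.csv", row.names = FALSE)
jsonlite::write_json(
  list(transforms = as.list(proc$transform_record),
       detection_limits = as.list(proc$detection_limit),
       missing_rates = as.list(colMeans(proc$missing_mask)),
       excluded = filt$excluded),
  "results/transforms.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("wrote results/processed_panel.csv, results/analysis_cohort.csv, results/transforms.json\n")
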