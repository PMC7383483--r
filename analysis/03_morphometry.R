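#!/usr/bin/env Rscript
# Per-tooth morphometry of the cohort generated by 01_generate_cohort.R:
# crown/root lengths, crown diameters, inclination and direction, cusp
# counts and crown types. Writes results/measurements.csv.

suppressPackageStartupMessages(library(supradent3d))

cohort_dir <- "results/cohort"
if (!dir.exists(cohort_dir)) stop("run analysis/01_generate_cohort.R first")
files <- list.files(cohort_dir, pattern = "^case-[0-9]+\\.json$", full.names = TRUE)

meas <- do.call(rbind, lapply(files, function(f) {
  d <- read_dentition(f)
  cbind(case_id = d$case_id, measurement_table(d))
}))
dir.create("results", showWarnings = FALSE)
utils::write.csv(meas, "results/measurements.csv", row.names = FALSE)

sup <- meas[meas$status == "supernumerary", ]
cat(sprintf("%d teeth measured, %d supernumerary\n", nrow(meas), nrow(sup)))
cat("\nSupernumerary crown types by region:\n")
print(table(sup$region, sup$crown_type, useNA = "ifany"))
cat(sprintf("\nAll permanent teeth in normal direction: %s\n",
            all(meas$direction[meas$status != "supernumerary"] == "normal")))
cat(sprintf("Supernumerary teeth in inverse direction: %d/%d\n",
            sum(sup$direction == "inverse"), nrow(sup)))
cat(sprintf("Roots excluded (out of imaging range): %d\n",
            sum(is.na(meas$root_length))))
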