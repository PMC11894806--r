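#!/usr/bin/env Rscript
# Stage 5: longitudinal validation and post-hoc comparisons.
#
# Subtype stability and stage progression of follow-up scans under the
# baseline-trained model, pathology-by-subtype enrichment, per-region
# volume comparisons between subtypes (all 24 regions, Bonferroni) and
# the laterality index.

suppressMessages(library(sustainz))

out <- "results/validate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scans <- read.csv("results/cohort/scans.csv", stringsAsFactors = FALSE)
adjusted <- read.csv("results/harmonize/adjusted_volumes.csv",
                     check.names = FALSE, stringsAsFactors = FALSE)
flat <- read.csv("results/assign/assignments.csv",
                 stringsAsFactors = FALSE)
schema <- default_region_schema()

stab <- subtype_stability(flat)
print(stab)
prog <- stage_progression(flat)
print(prog)

enr <- enrichment_test(flat)
print(enr)

rc <- regional_comparison(adjusted, flat, schema)
sig <- rc[!is.na(rc$p_bonferroni) & rc$p_bonferroni < 0.05, ]
cat(sprintf("regions differing between subtypes after Bonferroni: %d/%d\n",
            nrow(sig), sum(!rc$skipped)))
write.csv(rc, file.path(out, "regional_comparisons.csv"),
          row.names = FALSE)

lat <- suppressWarnings(
  laterality_comparison(scans[scans$group == "case", ], flat, schema))
print(lat)

report <- list(
  stability = stab$stability,
  n_stable = stab$n_stable,
  n_subtypable_followups = stab$n_followups,
  progression = setNames(as.list(prog$overall$proportion),
                         prog$overall$outcome),
  enrichment = list(statistic = enr$statistic, df = enr$df,
                    p = enr$p_value,
                    counts = as.data.frame.matrix(enr$counts)),
  n_regions_significant = nrow(sig)
)
jsonlite::write_json(report, file.path(out, "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", file.path(out, "report.json"), "\n")
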