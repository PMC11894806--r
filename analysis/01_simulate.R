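#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 252 controls and 135 cases with covariate effects on 24 regional
# grey-matter volumes; two latent atrophy subtypes (subcortical-first,
# 46%; cortical-first, 54%) over a 19-region event grid with thresholds
# z = 1, 2, 3; half the cases get 1-3 follow-up scans ~1.04 years apart
# with Poisson(1.5) latent stage advances.

suppressMessages(library(sustainz))

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

settings <- cohort_settings(seed = 20260924L)

cohort <- generate_cohort(settings)
followups <- generate_followups(cohort, settings)
scans <- rbind(cohort$scans, followups$scans)
truth <- rbind(cohort$truth, followups$truth)

write.csv(scans, file.path(out, "scans.csv"), row.names = FALSE)
write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE)

n_fu_subj <- length(unique(followups$truth$subject_id))
cat(sprintf("cohort: %d controls, %d baseline cases, %d follow-up scans from %d cases\n",
            sum(scans$group == "control"),
            sum(scans$group == "case" & scans$visit == 0),
            nrow(followups$scans), n_fu_subj))
cat(sprintf("latent subtypes: %s\n",
            paste(table(cohort$truth$subtype, useNA = "no"),
                  collapse = " / ")))
cat("wrote", file.path(out, "scans.csv"), "and truth.csv\n")
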