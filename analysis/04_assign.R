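#!/usr/bin/env Rscript
# Stage 4: assign every case scan (baseline and follow-up) to its
# maximum-likelihood subtype and stage under the trained model. Stage-0
# scans are flagged normal appearing.

suppressMessages(library(sustainz))

out <- "results/assign"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scans <- read.csv("results/cohort/scans.csv", stringsAsFactors = FALSE)
zt <- read.csv("results/harmonize/zscores.csv", check.names = FALSE,
               stringsAsFactors = FALSE)
Z <- as.matrix(zt[-1L])
rownames(Z) <- zt$scan_id
model <- read_model("results/fit/model.json")

case <- scans$group == "case"
assignments <- assign_cohort(Z[scans$scan_id[case], , drop = FALSE],
                             model, meta = scans)
flat <- as.data.frame(assignments)
flat$stage_posterior <- vapply(flat$stage_posterior, function(p)
  as.character(jsonlite::toJSON(p, digits = NA)), character(1))
write.csv(flat, file.path(out, "assignments.csv"), row.names = FALSE)

base <- assignments[assignments$visit == 0L, ]
cat(sprintf("baseline: %d/%d normal appearing (%.0f%%)\n",
            sum(base$normal_appearing), nrow(base),
            100 * mean(base$normal_appearing)))
for (c in sort(unique(base$ml_subtype[!base$normal_appearing]))) {
  sel <- base$ml_subtype == c & !base$normal_appearing
  cat(sprintf("subtype %d: %d scans, mean subtype probability %.2f\n",
              c, sum(sel), mean(base$subtype_prob[sel])))
}
cat("wrote", file.path(out, "assignments.csv"), "\n")
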