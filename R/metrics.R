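# Ground-truth recovery metrics for simulation studies.

#' Event positions of a sequence
#'
#' @param s an event sequence (event id at positions 1..N).
#' @return Integer vector: position of event 1..N.
#' @export
sequence_positions <- function(s) match(seq_along(s), s)

#' Kendall rank correlation between two event sequences
#'
#' Computed on the per-event positions, so 1 means identical orderings and
#' -1 fully reversed.
#'
#' @param a,b event sequences over the same grid.
#' @return Kendall's tau (scalar).
#' @export
sequence_kendall <- function(a, b) {
  cor(sequence_positions(a), sequence_positions(b), method = "kendall")
}

#' Match fitted subtypes to ground-truth sequences
#'
#' Tries every permutation of fitted subtypes against the true sequences
#' and keeps the one with the highest mean Kendall tau.
#'
#' @param fitted list of fitted event sequences.
#' @param truth list of true event sequences (same length).
#' @return List: `perm` (fitted index assigned to each truth index),
#'   `tau` (per-truth-subtype tau under the match), `mean_tau`.
#' @export
match_sequences <- function(fitted, truth) {
  C <- length(truth)
  stopifnot(length(fitted) == C)
  perms <- all_permutations(C)
  best <- NULL
  for (p in perms) {
    tau <- vapply(seq_len(C), function(c)
      sequence_kendall(fitted[[p[c]]], truth[[c]]), numeric(1))
    if (is.null(best) || mean(tau) > best$mean_tau) {
      best <- list(perm = p, tau = tau, mean_tau = mean(tau))
    }
  }
  best
}

# All permutations of 1..n (n small).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Parameter-recovery summary against a synthetic ground truth
#'
#' Matches fitted subtypes to the generating sequences, then reports the
#' per-subtype Kendall tau, the largest absolute error in the mixture
#' fractions, the maximum-likelihood subtype accuracy over scans that are
#' subtypable both in truth and in the assignment (stage > 0), and the
#' Spearman correlation between true and assigned stages.
#'
#' @param model a fitted [subtype_model()].
#' @param assignments [assign_cohort()] output for the same scans.
#' @param truth truth table from [generate_cohort()] restricted to the
#'   assigned scans (matched by `scan_id`).
#' @param settings the generating [cohort_settings()] (for the true
#'   sequences and fractions).
#' @return List: `tau` (per true subtype), `min_tau`, `fraction_error`,
#'   `subtype_accuracy`, `stage_spearman`.
#' @export
recovery_metrics <- function(model, assignments, truth, settings) {
  m <- match_sequences(model$sequences, settings$true_sequences)
  a <- as.data.frame(assignments)
  i <- match(a$scan_id, truth$scan_id)
  true_sub <- truth$subtype[i]
  true_stage <- truth$stage[i]
  # fitted subtype relabelled into truth indexing
  relabel <- match(a$ml_subtype, m$perm)
  ok <- !is.na(true_sub) & true_stage > 0 & a$ml_stage > 0
  list(tau = m$tau, min_tau = min(m$tau),
       fraction_error = max(abs(model$fractions[m$perm] -
                                  settings$true_fractions)),
       subtype_accuracy = mean(relabel[ok] == true_sub[ok]),
       stage_spearman = cor(a$ml_stage[!is.na(true_stage)],
                            true_stage[!is.na(true_stage)],
                            method = "spearman"))
}
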