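# Maximum-likelihood subtype and stage assignment of scans under a trained
# model, with the stage-0 "normal appearing" rule: scans whose most likely
# stage is 0 show no detectable atrophy relative to controls and carry no
# subtype label in downstream reports.

#' Assign scans to their maximum-likelihood subtype and stage
#'
#' For each scan, the subtype posterior is proportional to
#' fraction x stage-marginal likelihood; the maximum-likelihood subtype is
#' chosen first, then the stage maximizing the stage posterior under that
#' subtype. Ties break toward the lower subtype index / lower stage. Scans
#' with ML stage 0 are flagged normal appearing. With
#' `joint = TRUE` the (subtype, stage) pair maximizing the joint posterior
#' is taken instead.
#'
#' @param X z-score matrix, scans x model biomarkers; row names are scan
#'   ids.
#' @param model a trained [subtype_model()].
#' @param meta optional data frame with `scan_id`, `subject_id`, `visit`
#'   columns to merge into the output.
#' @param joint use joint (subtype, stage) maximization instead of
#'   subtype-then-stage?
#' @return Data frame of class `assignment` with one row per scan:
#'   `scan_id`, `ml_subtype`, `subtype_prob`, `ml_stage`,
#'   `normal_appearing`, plus one `subtype_prob_c<k>` column per subtype
#'   and the stage posterior as a `stage_posterior` list column.
#' @export
assign_cohort <- function(X, model, meta = NULL, joint = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$grid$biomarkers)) {
    stop("X has ", ncol(X), " biomarkers; model expects ",
         length(model$grid$biomarkers))
  }
  n <- nrow(X)
  C <- length(model$sequences)
  N <- model$grid$n_events
  ids <- rownames(X) %||% as.character(seq_len(n))
  if (n == 0L) {
    out <- data.frame(scan_id = character(0), ml_subtype = integer(0),
                      subtype_prob = numeric(0), ml_stage = integer(0),
                      normal_appearing = logical(0))
    class(out) <- c("assignment", "data.frame")
    return(out)
  }
  # per-subtype stage log-likelihood matrices (n x (N+1))
  stage_ll <- lapply(model$trajectories, function(tr)
    stage_loglik_matrix(X, tr, model$sigma))
  subj_ll <- vapply(stage_ll, function(m) row_logsumexp(m) - log(N + 1L),
                    numeric(n))
  subj_ll <- matrix(subj_ll, nrow = n)
  lw <- sweep(subj_ll, 2L,
              ifelse(model$fractions > 0, log(model$fractions), -Inf), "+")
  post <- exp(lw - row_logsumexp(lw))

  if (joint) {
    # joint posterior over (subtype, stage)
    ml_subtype <- integer(n); ml_stage <- integer(n)
    for (i in seq_len(n)) {
      jm <- vapply(seq_len(C), function(c) stage_ll[[c]][i, ],
                   numeric(N + 1L))
      jm <- sweep(matrix(jm, N + 1L, C), 2L,
                  ifelse(model$fractions > 0, log(model$fractions), -Inf),
                  "+")
      idx <- which(jm == max(jm), arr.ind = TRUE)[1L, ]
      ml_stage[i] <- idx[1L] - 1L
      ml_subtype[i] <- idx[2L]
    }
  } else {
    ml_subtype <- max.col(post, ties.method = "first")
    ml_stage <- vapply(seq_len(n), function(i)
      which.max(stage_ll[[ml_subtype[i]]][i, ]) - 1L, integer(1))
  }
  stage_post <- lapply(seq_len(n), function(i) {
    v <- stage_ll[[ml_subtype[i]]][i, ]
    exp(v - logsumexp(v))
  })
  out <- data.frame(scan_id = ids, ml_subtype = ml_subtype,
                    subtype_prob = post[cbind(seq_len(n), ml_subtype)],
                    ml_stage = ml_stage,
                    normal_appearing = ml_stage == 0L,
                    stringsAsFactors = FALSE)
  colnames(post) <- paste0("subtype_prob_c", seq_len(C))
  out <- cbind(out, as.data.frame(post))
  out$stage_posterior <- stage_post
  if (!is.null(meta)) {
    keep <- intersect(c("scan_id", "subject_id", "visit", "group",
                        "pathology"), names(meta))
    out <- merge(meta[keep], out, by = "scan_id", sort = FALSE)
  }
  class(out) <- c("assignment", "data.frame")
  out
}

#' Assign a single scan
#'
#' Convenience wrapper around [assign_cohort()] for one z-score vector.
#'
#' @param x numeric z-score vector (one entry per model biomarker).
#' @param model a trained [subtype_model()].
#' @inheritParams assign_cohort
#' @return One-row assignment data frame (see [assign_cohort()]).
#' @export
assign_scan <- function(x, model, joint = FALSE) {
  if (length(x) != length(model$grid$biomarkers)) {
    stop("x must have one entry per model biomarker")
  }
  assign_cohort(matrix(x, nrow = 1L), model, joint = joint)
}
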