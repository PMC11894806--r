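# Longitudinal validation metrics, subtype-pathology enrichment and
# subtype-wise regional / laterality comparisons.

# Link each follow-up assignment to its subject's baseline and immediately
# preceding assignment. Errors if a follow-up has no baseline.
link_followups <- function(assignments) {
  a <- as.data.frame(assignments)
  need <- c("scan_id", "subject_id", "visit", "ml_subtype", "ml_stage",
            "normal_appearing")
  missing <- setdiff(need, names(a))
  if (length(missing)) {
    stop("assignments lack column(s): ", paste(missing, collapse = ", "),
         " (pass meta = scans to assign_cohort)")
  }
  fu <- a[a$visit > 0L, ]
  base <- a[a$visit == 0L, ]
  orphans <- setdiff(fu$subject_id, base$subject_id)
  if (length(orphans)) {
    stop("follow-up without baseline for subject(s): ",
         paste(orphans, collapse = ", "))
  }
  if (nrow(fu) == 0L) return(fu)
  ib <- match(fu$subject_id, base$subject_id)
  fu$base_subtype <- base$ml_subtype[ib]
  fu$base_stage <- base$ml_stage[ib]
  fu$base_normal <- base$normal_appearing[ib]
  fu$base_subtype_prob <- base$subtype_prob[ib]
  # stage of the immediately preceding visit
  prev_stage <- integer(nrow(fu))
  prev_subtype <- integer(nrow(fu))
  for (i in seq_len(nrow(fu))) {
    cand <- a[a$subject_id == fu$subject_id[i] & a$visit < fu$visit[i], ]
    j <- which.max(cand$visit)
    prev_stage[i] <- cand$ml_stage[j]
    prev_subtype[i] <- cand$ml_subtype[j]
  }
  fu$prev_stage <- prev_stage
  fu$prev_subtype <- prev_subtype
  fu
}

#' Subtype stability at follow-up
#'
#' A subtypable follow-up scan counts stable when it keeps its baseline
#' subtype, or when the baseline was normal appearing (stage 0) and the
#' scan became subtypable. Follow-ups that are themselves normal appearing
#' are excluded from the denominator (they are not subtypable).
#'
#' @param assignments an [assign_cohort()] result carrying `subject_id`
#'   and `visit` (pass `meta = scans`).
#' @return Object of class `stability_report`: `n_followups` (subtypable
#'   follow-up scans), `n_stable`, `stability`, `transitions`
#'   (baseline-subtype x follow-up-subtype counts, baseline row `stage0`
#'   for normal-appearing baselines), and `switchers` (subjects changing
#'   subtype, with their baseline subtype probability).
#' @export
subtype_stability <- function(assignments) {
  fu <- link_followups(assignments)
  fu <- fu[!fu$normal_appearing, ]            # subtypable follow-ups only
  n <- nrow(fu)
  stable <- fu$base_normal | (fu$ml_subtype == fu$base_subtype)
  C <- max(c(assignments$ml_subtype, 1L))
  from <- character(n)
  if (n) from <- ifelse(fu$base_normal, "stage0",
                        paste0("c", fu$base_subtype))
  to <- if (n) paste0("c", fu$ml_subtype) else character(0)
  transitions <- table(factor(from, levels = c("stage0",
                                               paste0("c", seq_len(C)))),
                       factor(to, levels = paste0("c", seq_len(C))))
  switchers <- fu[!stable,
                  c("scan_id", "subject_id", "visit", "base_subtype",
                    "ml_subtype", "base_subtype_prob")]
  structure(list(n_followups = n, n_stable = sum(stable),
                 stability = if (n) sum(stable) / n else NA_real_,
                 transitions = transitions, switchers = switchers),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("subtype stability: %d/%d (%.1f%%) of subtypable follow-ups\n",
              x$n_stable, x$n_followups, 100 * x$stability))
  invisible(x)
}

#' Stage progression at follow-up
#'
#' Each follow-up scan is compared with the subject's immediately
#' preceding visit (default) or with the baseline scan, and classified as
#' advanced, same or regressed. Proportions are reported overall and per
#' baseline subtype, counting follow-up comparisons (scans); a per-subject
#' view classifying baseline vs last follow-up is also included.
#'
#' @inheritParams subtype_stability
#' @param against compare with the `"previous"` visit (default) or the
#'   `"baseline"` scan.
#' @return Object of class `progression_report`: `overall` and
#'   `by_subtype` count/proportion tables and `subjects` (per-subject
#'   baseline-vs-last classification).
#' @export
stage_progression <- function(assignments, against = c("previous",
                                                       "baseline")) {
  against <- match.arg(against)
  fu <- link_followups(assignments)
  ref <- if (against == "previous") fu$prev_stage else fu$base_stage
  cls <- function(now, before) {
    factor(ifelse(now > before, "advanced",
                  ifelse(now == before, "same", "regressed")),
           levels = c("advanced", "same", "regressed"))
  }
  fu$outcome <- cls(fu$ml_stage, ref)
  tab <- function(f) {
    counts <- table(f)
    data.frame(outcome = names(counts), n = as.integer(counts),
               proportion = as.numeric(counts) / max(1L, sum(counts)))
  }
  by_subtype <- lapply(split(fu$outcome, fu$base_subtype), tab)
  # per-subject: baseline vs last follow-up
  last <- fu[order(fu$subject_id, fu$visit), ]
  last <- last[!duplicated(last$subject_id, fromLast = TRUE), ]
  subjects <- data.frame(subject_id = last$subject_id,
                         outcome = cls(last$ml_stage, last$base_stage))
  structure(list(overall = tab(fu$outcome), by_subtype = by_subtype,
                 n_comparisons = nrow(fu), subjects = subjects),
            class = "progression_report")
}

#' @export
print.progression_report <- function(x, ...) {
  cat("stage progression over", x$n_comparisons,
      "follow-up comparisons:\n")
  print(x$overall)
  invisible(x)
}

#' Pathology-by-subtype enrichment test
#'
#' Pearson's chi-squared test (no continuity correction) on the pathology
#' x subtype contingency table of subtypable scans. Accepts either an
#' assignment table (labelled pathologies, normal-appearing scans and
#' unlabelled scans excluded) or a ready-made count matrix.
#'
#' @param x an [assign_cohort()] result with a `pathology` column, or a
#'   numeric contingency matrix (rows = pathologies, columns = subtypes).
#' @return Object of class `enrichment_table`: `counts`, `row_percent`,
#'   `statistic`, `df`, `p_value`, `low_expected` (any expected count
#'   below 5, reported as a caveat, not a method switch).
#' @export
enrichment_test <- function(x) {
  if (is.matrix(x)) {
    counts <- x
  } else {
    a <- as.data.frame(x)
    keep <- !a$normal_appearing & !is.na(a$pathology) &
      a$pathology != "none"
    if (!is.null(a$visit)) keep <- keep & a$visit == 0L  # one scan per case
    counts <- as.matrix(table(a$pathology[keep], a$ml_subtype[keep]))
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("degenerate contingency table (need >= 2 rows and columns)")
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected counts below 5; chi-squared approximation is rough")
  }
  structure(list(counts = counts,
                 row_percent = 100 * counts / rowSums(counts),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 low_expected = any(ht$expected < 5)),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("chi-squared = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Regional volume comparisons between subtypes
#'
#' Pairwise two-tailed unpaired t-tests (pooled variance by default) on
#' baseline adjusted volumes of every schema region between every pair of
#' subtypes, over subtypable baseline scans. P-values are Bonferroni
#' adjusted over the whole family of tests performed; the direction column
#' names the subtype with the smaller mean volume.
#'
#' @param adjusted combined, covariate-adjusted scan table.
#' @param assignments an [assign_cohort()] result for the same scans.
#' @param schema a [region_schema()].
#' @param welch use Welch's t-test instead of the pooled-variance test?
#' @return Data frame: region, pair, t, p, p_bonferroni, lower_group,
#'   skipped (zero-variance guard).
#' @export
regional_comparison <- function(adjusted, assignments, schema,
                                welch = FALSE) {
  a <- merge(adjusted, as.data.frame(assignments)[
    c("scan_id", "ml_subtype", "normal_appearing")], by = "scan_id")
  a <- a[a$visit == 0L & !a$normal_appearing & a$group == "case", ]
  subtypes <- sort(unique(a$ml_subtype))
  if (length(subtypes) < 2L) stop("need at least two subtypes to compare")
  pairs <- combn(subtypes, 2L, simplify = FALSE)
  rows <- list()
  for (r in schema$region) {
    for (pr in pairs) {
      g1 <- a[[r]][a$ml_subtype == pr[1L]]
      g2 <- a[[r]][a$ml_subtype == pr[2L]]
      if (length(g1) < 2L || length(g2) < 2L ||
          (var(g1) == 0 && var(g2) == 0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, pair = paste0("c", pr[1L], "-c", pr[2L]),
          t = NA_real_, p = NA_real_, lower_group = NA_character_,
          skipped = TRUE)
        next
      }
      ht <- t.test(g1, g2, var.equal = !welch)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, pair = paste0("c", pr[1L], "-c", pr[2L]),
        t = unname(ht$statistic), p = ht$p.value,
        lower_group = paste0("c", pr[if (mean(g1) < mean(g2)) 1L else 2L]),
        skipped = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(!out$skipped)
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

#' Laterality index comparisons between groups and visits
#'
#' Computes the scan-level laterality index, summarizes mean (SD) per
#' group and visit, and runs two-tailed t-tests between groups at baseline
#' and between baseline and follow-up within each group, Bonferroni
#' adjusted over the family of tests. Groups default to the assigned
#' subtype of subtypable scans; any label vector can be supplied instead.
#'
#' @param scans raw scan table with per-hemisphere columns.
#' @param assignments an [assign_cohort()] result (with meta), or `NULL`
#'   when `labels` is given.
#' @param schema a [region_schema()].
#' @param labels optional named character vector (names = scan ids) of
#'   group labels overriding subtype grouping.
#' @param welch use Welch's t-test?
#' @return List of class `laterality_report`: `summary` (group x visit
#'   mean/SD/n) and `tests` (comparison, t, p, p_bonferroni, skipped).
#' @export
laterality_comparison <- function(scans, assignments = NULL, schema,
                                  labels = NULL, welch = FALSE) {
  li <- laterality_index(scans, schema)
  d <- data.frame(scan_id = scans$scan_id, visit = scans$visit, li = li,
                  stringsAsFactors = FALSE)
  if (is.null(labels)) {
    a <- as.data.frame(assignments)
    a <- a[!a$normal_appearing, c("scan_id", "ml_subtype")]
    a$label <- paste0("c", a$ml_subtype)
    d <- merge(d, a[c("scan_id", "label")], by = "scan_id")
  } else {
    d$label <- labels[d$scan_id]
    d <- d[!is.na(d$label), ]
  }
  d$phase <- ifelse(d$visit == 0L, "baseline", "followup")
  agg <- aggregate(li ~ label + phase, d,
                   function(v) c(mean = mean(v), sd = sd(v),
                                 n = length(v)))
  summary <- data.frame(agg[c("label", "phase")],
                        mean = agg$li[, "mean"], sd = agg$li[, "sd"],
                        n = agg$li[, "n"])
  tests <- list()
  add_test <- function(name, g1, g2) {
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("skipping '", name, "': a group has fewer than 2 scans")
      tests[[length(tests) + 1L]] <<- data.frame(
        comparison = name, t = NA_real_, p = NA_real_, skipped = TRUE)
      return(invisible())
    }
    if (var(g1) == 0 && var(g2) == 0) {
      warning("skipping '", name, "': zero variance in both groups")
      tests[[length(tests) + 1L]] <<- data.frame(
        comparison = name, t = NA_real_, p = NA_real_, skipped = TRUE)
      return(invisible())
    }
    ht <- t.test(g1, g2, var.equal = !welch)
    tests[[length(tests) + 1L]] <<- data.frame(
      comparison = name, t = unname(ht$statistic), p = ht$p.value,
      skipped = FALSE)
  }
  labs <- sort(unique(d$label))
  if (length(labs) >= 2L) {
    for (pr in combn(labs, 2L, simplify = FALSE)) {
      add_test(paste0(pr[1L], " vs ", pr[2L], " (baseline)"),
               d$li[d$label == pr[1L] & d$phase == "baseline"],
               d$li[d$label == pr[2L] & d$phase == "baseline"])
    }
  }
  for (lb in labs) {
    g_fu <- d$li[d$label == lb & d$phase == "followup"]
    if (length(g_fu)) {
      add_test(paste0(lb, ": baseline vs follow-up"),
               d$li[d$label == lb & d$phase == "baseline"], g_fu)
    }
  }
  tests <- do.call(rbind, tests)
  m <- sum(!tests$skipped)
  tests$p_bonferroni <- pmin(1, tests$p * max(1L, m))
  structure(list(summary = summary, tests = tests, scans = d),
            class = "laterality_report")
}

#' @export
print.laterality_report <- function(x, ...) {
  print(x$summary)
  print(x$tests[c("comparison", "t", "p", "p_bonferroni")])
  invisible(x)
}
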