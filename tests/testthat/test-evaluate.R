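# Longitudinal stability/progression, enrichment, and post-hoc group
# comparisons.

mk_assign <- function(subject, visit, subtype, stage, prob = 0.9) {
  data.frame(scan_id = paste0(subject, "_v", visit),
             subject_id = subject, visit = visit,
             ml_subtype = subtype, ml_stage = stage,
             normal_appearing = stage == 0L, subtype_prob = prob,
             stringsAsFactors = FALSE)
}

test_that("subtype stability counts same-subtype and newly subtypable follow-ups", {
  a <- rbind(
    mk_assign("s1", 0L, 1L, 3L), mk_assign("s1", 1L, 1L, 4L),
    mk_assign("s2", 0L, 2L, 2L), mk_assign("s2", 1L, 2L, 2L),
    mk_assign("s3", 0L, 1L, 5L), mk_assign("s3", 1L, 1L, 6L),
    mk_assign("s4", 0L, 1L, 2L), mk_assign("s4", 1L, 1L, 3L))
  expect_equal(subtype_stability(a)$stability, 1.0)
  # one switch
  a$ml_subtype[a$scan_id == "s4_v1"] <- 2L
  r <- subtype_stability(a)
  expect_equal(r$stability, 0.75)
  expect_identical(r$switchers$subject_id, "s4")
  # a stage-0 baseline that becomes subtypable counts stable
  b <- rbind(mk_assign("s5", 0L, 1L, 0L), mk_assign("s5", 1L, 2L, 3L))
  expect_equal(subtype_stability(b)$stability, 1.0)
  # normal-appearing at both visits is excluded from the denominator
  c2 <- rbind(mk_assign("s6", 0L, 1L, 0L), mk_assign("s6", 1L, 1L, 0L))
  expect_identical(subtype_stability(c2)$n_followups, 0L)
  # orphan follow-ups are an error
  expect_error(subtype_stability(mk_assign("s7", 1L, 1L, 3L)), "s7")
})

test_that("stage progression classifies against the immediately preceding visit", {
  a <- rbind(
    mk_assign("s1", 0L, 1L, 2L), mk_assign("s1", 1L, 1L, 4L),  # advanced
    mk_assign("s2", 0L, 1L, 3L), mk_assign("s2", 1L, 1L, 3L),  # same
    mk_assign("s3", 0L, 2L, 5L), mk_assign("s3", 1L, 2L, 4L),  # regressed
    mk_assign("s4", 0L, 2L, 1L), mk_assign("s4", 1L, 2L, 2L),
    mk_assign("s4", 2L, 2L, 2L))                               # adv, same
  r <- stage_progression(a)
  counts <- setNames(r$overall$n, r$overall$outcome)
  expect_identical(counts[["advanced"]], 2L)
  expect_identical(counts[["same"]], 2L)
  expect_identical(counts[["regressed"]], 1L)
  expect_equal(sum(r$overall$proportion), 1)
  # against baseline: s4's second follow-up compares 2 vs 1 -> advanced
  rb <- stage_progression(a, against = "baseline")
  cb <- setNames(rb$overall$n, rb$overall$outcome)
  expect_identical(cb[["advanced"]], 3L)
  # per-subject view uses baseline vs last follow-up
  expect_identical(nrow(r$subjects), 4L)
})

test_that("noise-free synthetic longitudinal data never regresses", {
  st <- recovery_settings(seed = 63, n_cases = 60L, n_controls = 10L,
                          followup_fraction = 1)
  co <- generate_cohort(st)
  fu <- generate_followups(co, st)
  truth <- rbind(co$truth, fu$truth)
  truth <- truth[!is.na(truth$subtype), ]
  Z <- true_zscores(truth, st)
  model <- subtype_model(st$true_sequences, st$true_fractions, st$grid)
  a <- assign_cohort(Z, model,
                     meta = data.frame(scan_id = truth$scan_id,
                                       subject_id = truth$subject_id,
                                       visit = truth$visit))
  r <- stage_progression(a)
  expect_identical(sum(r$overall$n[r$overall$outcome == "regressed"]), 0L)
})

test_that("the enrichment chi-squared equals the hand-rolled statistic", {
  tab <- matrix(c(9, 5, 6, 36, 3, 1, 25, 38), ncol = 2,
                dimnames = list(c("CBD", "PSP", "AD", "IDT"), NULL))
  r <- suppressWarnings(enrichment_test(tab))
  # hand-rolled Pearson chi-squared
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_identical(r$df, 3L)
  expect_equal(r$p_value, pchisq(r$statistic, 3, lower.tail = FALSE))
  # identical row distributions give chi-squared 0, p = 1
  flat <- matrix(c(10, 20, 10, 20), ncol = 2)
  r0 <- suppressWarnings(enrichment_test(flat))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # degenerate tables are rejected
  expect_error(enrichment_test(matrix(c(3, 4), ncol = 1)), "degenerate")
})

test_that("regional comparisons find injected subtype differences, Bonferroni-adjusted", {
  st <- recovery_settings(seed = 73, n_cases = 300L, n_controls = 150L)
  z <- cohort_zscores(st)
  case <- z$scans$group == "case"
  model <- subtype_model(st$true_sequences, st$true_fractions, st$grid)
  a <- assign_cohort(z$Z[case, , drop = FALSE], model,
                     meta = z$scans[case, ])
  rc <- regional_comparison(z$adjusted, a, st$schema)
  # Bonferroni arithmetic: p = 0.01 with m tests
  m <- sum(!rc$skipped)
  expect_equal(rc$p_bonferroni, pmin(1, rc$p * m))
  expect_true(all(rc$p_bonferroni >= rc$p | is.na(rc$p)))
  # subtype 1 atrophies midbrain first -> midbrain lower in subtype 1;
  # subtype 2 starts in occipital
  row_mid <- rc[rc$region == "midbrain", ]
  row_occ <- rc[rc$region == "occipital", ]
  expect_identical(row_mid$lower_group, "c1")
  expect_identical(row_occ$lower_group, "c2")
  expect_lt(row_mid$p_bonferroni, 0.05)
  expect_lt(row_occ$p_bonferroni, 0.05)
  # regions with no subtype contrast are not flagged: identical groups
  a2 <- a
  a2$ml_subtype <- rep(c(1L, 2L), length.out = nrow(a2))
  rc2 <- regional_comparison(z$adjusted, a2, st$schema)
  expect_true(all(rc2$p_bonferroni > 0.05, na.rm = TRUE))
})

test_that("laterality comparisons detect asymmetry injected into one subtype", {
  st <- recovery_settings(seed = 83, n_cases = 250L, n_controls = 60L,
                          asymmetry = c(0.08, 0))
  co <- generate_cohort(st)
  model <- subtype_model(st$true_sequences, st$true_fractions, st$grid)
  truth <- co$truth[!is.na(co$truth$subtype), ]
  Z <- true_zscores(truth, st)
  a <- assign_cohort(Z, model,
                     meta = data.frame(scan_id = truth$scan_id,
                                       subject_id = truth$subject_id,
                                       visit = truth$visit))
  case_scans <- co$scans[co$scans$group == "case", ]
  r <- laterality_comparison(case_scans, a, st$schema)
  s <- r$summary
  expect_gt(s$mean[s$label == "c1"], s$mean[s$label == "c2"])
  t1 <- r$tests[grepl("c1 vs c2", r$tests$comparison), ]
  expect_lt(t1$p_bonferroni, 0.05)
})

test_that("a fully symmetric cohort triggers the zero-variance guard", {
  st <- recovery_settings(seed = 93, n_cases = 60L, n_controls = 20L)
  co <- generate_cohort(st)
  truth <- co$truth[!is.na(co$truth$subtype), ]
  model <- subtype_model(st$true_sequences, st$true_fractions, st$grid)
  a <- assign_cohort(true_zscores(truth, st), model,
                     meta = data.frame(scan_id = truth$scan_id,
                                       subject_id = truth$subject_id,
                                       visit = truth$visit))
  case_scans <- co$scans[co$scans$group == "case", ]
  # default generator is symmetric: every LI is exactly 0
  expect_true(all(laterality_index(case_scans, st$schema) == 0))
  expect_warning(r <- laterality_comparison(case_scans, a, st$schema),
                 "zero variance")
  expect_true(all(r$summary$mean == 0))
  expect_true(all(r$tests$skipped))
})
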