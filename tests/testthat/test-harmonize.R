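# Covariate harmonization, hemisphere combination, effect-size ROI
# selection, z-scoring and the laterality index.

# Minimal hand-built control table over a 2-region schema.
toy_schema <- region_schema(c("alpha", "beta"), paired = c(TRUE, FALSE),
                            group = c("cortical", "brainstem"))

toy_controls <- function(n = 60L, seed = 1, age_effect = 0,
                         field_effect = 0, noise = 0) {
  set.seed(seed)
  d <- data.frame(
    subject_id = sprintf("c%02d", seq_len(n)),
    scan_id = sprintf("c%02d_v0", seq_len(n)),
    visit = 0L, group = "control", pathology = "none",
    age = runif(n, 50, 80),
    sex = sample(c("F", "M"), n, replace = TRUE),
    tiv = runif(n, 1.2e6, 1.6e6),
    field_strength = sample(c("1.5T", "3T"), n, replace = TRUE),
    manufacturer = sample(c("GE", "Siemens"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  base <- 1000 + age_effect * (d$age - 60) +
    field_effect * (d$field_strength == "3T") + rnorm(n, 0, noise)
  d$alpha <- base
  d$beta <- base + 500
  d
}

test_that("OLS recovers a noiseless age slope exactly", {
  ctl <- toy_controls(age_effect = -2)
  hm <- fit_covariate_model(ctl, toy_schema)
  expect_equal(unname(hm$coefficients["age", "alpha"]), -2,
               tolerance = 1e-8)
  expect_equal(unname(hm$coefficients["age", "beta"]), -2,
               tolerance = 1e-8)
})

test_that("zero covariate effects leave volumes unchanged after adjustment", {
  ctl <- toy_controls(noise = 0)
  hm <- fit_covariate_model(ctl, toy_schema)
  adj <- apply_harmonization(ctl, hm)
  expect_equal(adj$alpha, ctl$alpha, tolerance = 1e-8)
  expect_equal(adj$beta, ctl$beta, tolerance = 1e-8)
})

test_that("a single-level categorical raises a singular-design error naming it", {
  ctl <- toy_controls()
  ctl$manufacturer <- "Siemens"
  expect_error(fit_covariate_model(ctl, toy_schema), "manufacturer")
})

test_that("modeled covariate differences are removed by adjustment", {
  ctl <- toy_controls(age_effect = -2, noise = 0)
  hm <- fit_covariate_model(ctl, toy_schema)
  two <- ctl[c(1L, 1L), ]
  two$scan_id <- c("s1", "s2")
  two$age[2L] <- two$age[2L] + 10
  two$alpha[2L] <- two$alpha[2L] - 20      # the modeled -2/year effect
  two$beta[2L] <- two$beta[2L] - 20
  adj <- apply_harmonization(two, hm)
  expect_equal(adj$alpha[1L], adj$alpha[2L], tolerance = 1e-8)
})

test_that("unseen categorical levels are rejected by name", {
  ctl <- toy_controls()
  hm <- fit_covariate_model(ctl, toy_schema)
  new <- ctl[1L, ]
  new$manufacturer <- "Philips"
  expect_error(apply_harmonization(new, hm), "Philips")
})

test_that("an injected scanner offset is removed to within 1 SE", {
  st <- recovery_settings(seed = 19, n_cases = 100L, n_controls = 200L)
  z <- cohort_zscores(st)
  adj <- z$adjusted[z$adjusted$group == "control", ]
  for (r in c("midbrain", "parietal")) {
    fit <- summary(lm(adj[[r]] ~ (adj$field_strength == "3T") + adj$age))
    expect_lt(abs(fit$coefficients[2L, "t value"]), 1)
    expect_lt(abs(fit$coefficients[3L, "t value"]), 1)
  }
})

test_that("hemisphere combination sums pairs and conserves total volume", {
  raw <- data.frame(subject_id = "s", scan_id = "s_v0", visit = 0L,
                    group = "case", pathology = "none", age = 60,
                    sex = "F", tiv = 1.4e6, field_strength = "3T",
                    manufacturer = "GE",
                    alpha_L = 10, alpha_R = 12, beta = 7)
  cmb <- combine_hemispheres(raw, toy_schema)
  expect_equal(cmb$alpha, 22)
  expect_equal(cmb$beta, 7)
  expect_equal(cmb$alpha + cmb$beta, raw$alpha_L + raw$alpha_R + raw$beta)
  expect_error(combine_hemispheres(raw[setdiff(names(raw), "alpha_R")],
                                   toy_schema), "alpha")
})

test_that("Cohen's d follows the pooled n-1 convention", {
  expect_equal(cohens_d(cases = c(1, 2, 3), controls = c(1, 2, 3)), 0)
  # means 9 and 10, both SD exactly 1, equal n
  set.seed(2)
  g1 <- as.numeric(scale(rnorm(30))) + 9
  g2 <- as.numeric(scale(rnorm(30))) + 10
  expect_equal(cohens_d(cases = g1, controls = g2), 1, tolerance = 1e-12)
  # hand-evaluated: means 9 and 11, both variances 1, pooled SD 1
  expect_equal(cohens_d(cases = c(8, 9, 10), controls = c(10, 11, 12)), 2)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("ROI selection keeps exactly the regions with injected effects", {
  st <- recovery_settings(seed = 23, n_cases = 200L, n_controls = 200L)
  z <- cohort_zscores(st)
  sel <- select_rois(z$adjusted, st$schema, threshold = 0.6)
  expect_identical(sort(sel$regions), sort(st$grid$biomarkers))
  # threshold 0 keeps all 24
  sel0 <- select_rois(z$adjusted, st$schema, threshold = 0)
  expect_identical(sel0$regions, st$schema$region)
  # monotone: raising the threshold never adds a region
  for (th in c(0.3, 0.8, 1.2, 2)) {
    expect_true(all(select_rois(z$adjusted, st$schema, th)$regions %in%
                      sel0$regions))
  }
  sel_hi <- select_rois(z$adjusted, st$schema, 1.0)
  expect_true(all(sel_hi$regions %in% sel$regions))
})

test_that("z-scores are atrophy-positive and standardized in-sample", {
  ctl <- toy_controls(age_effect = -2, noise = 5)
  hm <- fit_covariate_model(ctl, toy_schema)
  adj <- apply_harmonization(ctl, hm)
  Z <- to_zscores(adj, hm, c("alpha", "beta"))
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-8)
  # one control SD below the mean maps to z = +1
  probe <- adj[1L, ]
  probe$alpha <- hm$ctrl_mean["alpha"] - hm$ctrl_sd["alpha"]
  probe$beta <- hm$ctrl_mean["beta"]
  zp <- to_zscores(probe, hm, c("alpha", "beta"))
  expect_equal(unname(zp[1L, ]), c(1, 0), tolerance = 1e-12)
  # affine map: within-region rank order is reversed
  expect_identical(order(Z[, "alpha"]), rev(order(adj$alpha)))
})

test_that("adjusted control volumes are orthogonal to modeled covariates", {
  st <- recovery_settings(seed = 29, n_cases = 30L, n_controls = 150L)
  z <- cohort_zscores(st)
  adj <- z$adjusted[z$adjusted$group == "control", ]
  for (r in c("midbrain", "occipital")) {
    expect_lt(abs(cor(adj[[r]], adj$age)), 1e-6)
    expect_lt(abs(cor(adj[[r]], adj$tiv)), 1e-6)
    expect_lt(abs(cor(adj[[r]], as.numeric(adj$sex == "M"))), 1e-6)
  }
})

test_that("the laterality index is |L - R| over total volume, in percent", {
  schema <- region_schema(c("p", "m"), paired = c(TRUE, FALSE),
                          group = c("cortical", "brainstem"))
  sc <- data.frame(subject_id = "s", scan_id = "s_v0", visit = 0L,
                   group = "case", pathology = "none", age = 60,
                   sex = "F", tiv = 1.4e6, field_strength = "3T",
                   manufacturer = "GE",
                   p_L = 505, p_R = 485, m = 10)
  # symmetric scan
  sym <- sc
  sym$p_L <- sym$p_R <- 500
  expect_equal(unname(laterality_index(sym, schema)), 0)
  # left 505, right 485, total 1000 -> LI = 2.0
  li <- unname(laterality_index(sc, schema))
  expect_equal(li, 2.0)
  # scale invariance
  sc2 <- sc
  for (cl in c("p_L", "p_R", "m")) sc2[[cl]] <- 2 * sc2[[cl]]
  expect_equal(unname(laterality_index(sc2, schema)), li)
})
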