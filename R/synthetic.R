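# Synthetic cohort generator with known subtype/stage ground truth.
#
# The generator emulates the statistical structure of a multi-centre
# volumetric MRI study of corticobasal syndrome: ~252 controls and ~135
# cases scanned at 1.5T/3T on two manufacturers, covariate effects of age,
# sex and head size on regional volumes, 2-3 latent atrophy subtypes with
# distinct event orderings, uniform stage occupancy among cases, and
# ~1-year follow-up scans with non-decreasing latent stage.

# Typical control-level combined (left+right) volumes in mm^3. Values are
# plausible magnitudes for the default atlas, not measurements.
default_region_stats <- function(schema) {
  means <- c(
    medulla = 4600, pons = 14800, scp = 620, midbrain = 6300,
    cerebellar_cortex = 104000, dentate = 2100, vermis = 9800,
    thalamus = 15400, globus_pallidus = 3300, caudate = 7200,
    putamen = 9800, ventral_dc = 8200, hippocampus = 7400,
    amygdala = 3100, accumbens = 1050, basal_forebrain = 820,
    cingulate = 21000, corpus_callosum = 19500,
    frontal_anterior = 82000, frontal_posterior = 63000,
    insula = 14200, temporal = 92000, parietal = 61000, occipital = 42000
  )
  missing <- setdiff(schema$region, names(means))
  if (length(missing)) {
    # unknown custom regions get a generic size
    means[missing] <- 10000
  }
  means <- means[schema$region]
  list(mean = means, sd = 0.09 * means)
}

#' Build an event sequence from a biomarker ordering
#'
#' Biomarker-major (default): each biomarker crosses all its thresholds
#' before the next one starts -- maximally distinct subtypes when orders
#' differ. Interleaved (level-major): all first thresholds in `order`,
#' then all second thresholds, and so on -- overlapping progression, but
#' distinct orders become indistinguishable at the stage where every
#' biomarker sits at the same threshold.
#'
#' @param grid an [event_grid()].
#' @param order biomarker names or indices, each exactly once.
#' @param interleave use level-major interleaving?
#' @return A valid event sequence (integer vector).
#' @export
staged_sequence <- function(grid, order, interleave = FALSE) {
  if (is.character(order)) {
    order <- match(order, grid$biomarkers)
    if (anyNA(order)) stop("sequence references unknown biomarkers")
  }
  if (!setequal(order, seq_along(grid$biomarkers))) {
    stop("order must visit every biomarker exactly once")
  }
  ev <- grid$events
  if (interleave) {
    ids <- integer(0)
    for (lev in seq_len(max(ev$level))) {
      for (b in order) {
        ids <- c(ids, which(ev$biomarker == b & ev$level == lev))
      }
    }
    ids
  } else {
    unlist(lapply(order, function(b) which(ev$biomarker == b)))
  }
}

# The 19 modelled regions of the default schema (atrophy signal regions).
default_signal_regions <- function() {
  c("medulla", "pons", "scp", "midbrain", "cerebellar_cortex", "dentate",
    "thalamus", "globus_pallidus", "caudate", "putamen", "ventral_dc",
    "amygdala", "corpus_callosum", "frontal_anterior", "frontal_posterior",
    "insula", "temporal", "parietal", "occipital")
}

# Default subcortical-first and cortical-first region orderings.
default_subtype_orders <- function() {
  list(
    subcortical = c("scp", "midbrain", "pons", "medulla", "ventral_dc",
                    "dentate", "thalamus", "cerebellar_cortex",
                    "globus_pallidus", "caudate", "putamen", "amygdala",
                    "corpus_callosum", "frontal_posterior", "insula",
                    "parietal", "occipital", "frontal_anterior", "temporal"),
    cortical = c("parietal", "frontal_posterior", "insula", "occipital",
                 "temporal", "putamen", "globus_pallidus", "corpus_callosum",
                 "frontal_anterior", "caudate", "amygdala", "thalamus",
                 "ventral_dc", "cerebellar_cortex", "dentate", "midbrain",
                 "scp", "pons", "medulla")
  )
}

# Default P(pathology | subtype) matrices echoing observed subtype-by-
# pathology proportions for two- and three-subtype cohorts.
default_pathology_mixing <- function(n_subtypes) {
  paths <- c("CBD", "PSP", "AD", "IDT")
  if (n_subtypes == 2L) {
    m <- cbind(c(9, 5, 6, 36) / 56, c(3, 1, 25, 38) / 67)
  } else if (n_subtypes == 3L) {
    m <- cbind(c(2, 5, 3, 28) / 38, c(10, 1, 7, 38) / 56,
               c(0, 0, 21, 7) / 28)
  } else {
    m <- matrix(rep(c(0.09, 0.04, 0.23, 0.64), n_subtypes),
                nrow = 4L)
  }
  rownames(m) <- paths
  m
}

#' Settings for the synthetic cohort generator
#'
#' Bundles everything that defines a simulated study: cohort sizes, the
#' region schema and control-level volume statistics, the event grid and
#' true subtype sequences, covariate effects on volumes, the z-unit noise
#' level, left/right asymmetry, pathology mixing and the follow-up design.
#'
#' @param n_controls,n_cases cohort sizes (defaults 252 and 135).
#' @param schema a [region_schema()]; default [default_region_schema()].
#' @param grid an [event_grid()] over a subset of schema regions; default
#'   thresholds `{1, 2, 3}` (z_max 5) over the 19 signal regions.
#' @param true_sequences list of event sequences, one per latent subtype;
#'   default a subcortical-first and a cortical-first ordering.
#' @param true_fractions subtype mixture fractions (default `c(0.46, 0.54)`).
#' @param region_means,region_sds named per-region control mean/SD (mm^3,
#'   combined volumes); defaults from [default_region_stats].
#' @param age_slope,sex_offset,tiv_slope,field_offset,manufacturer_offset
#'   covariate effects on combined volumes: mm^3 per year of age relative
#'   to the cohort reference age (per-region vector or scalar fraction of
#'   the region mean), mm^3 added for male sex, dimensionless slope on TIV
#'   about its reference, and mm^3 offsets for 3T field strength and GE
#'   manufacturer. Scalars are interpreted as fractions of the region mean.
#' @param noise_sd measurement noise SD in z-units (default 1).
#' @param asymmetry per-subtype left/right volume imbalance fraction of
#'   each paired region (default 0 = symmetric; recycled over subtypes).
#' @param pathology_mixing `4 x C` matrix of P(pathology | subtype) with
#'   rows CBD, PSP, AD, IDT; default echoes observed proportions.
#' @param followup_fraction fraction of cases with follow-up (default 0.5).
#' @param n_followup_probs probabilities of 1, 2, 3 follow-up visits
#'   (default `c(0.39, 0.58, 0.03)`).
#' @param stage_increment distribution of latent stage advance per visit:
#'   `list(dist = "poisson", lambda = ...)` or
#'   `list(dist = "fixed", value = ...)`; must be non-negative.
#' @param followup_interval years between visits (default 1.04).
#' @param seed integer seed; every generator call is deterministic given it.
#' @return Object of class `cohort_settings`.
#' @export
cohort_settings <- function(n_controls = 252L, n_cases = 135L,
                            schema = default_region_schema(),
                            grid = NULL, true_sequences = NULL,
                            true_fractions = c(0.46, 0.54),
                            region_means = NULL, region_sds = NULL,
                            age_slope = -0.004, sex_offset = 0.035,
                            tiv_slope = 0.35, field_offset = 0.01,
                            manufacturer_offset = -0.006,
                            noise_sd = 1, asymmetry = 0,
                            pathology_mixing = NULL,
                            followup_fraction = 0.5,
                            n_followup_probs = c(0.39, 0.58, 0.03),
                            stage_increment = list(dist = "poisson",
                                                   lambda = 1.5),
                            followup_interval = 1.04,
                            seed = 1L) {
  if (n_controls <= 0 || n_cases <= 0) stop("cohort sizes must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  stats <- default_region_stats(schema)
  if (is.null(region_means)) region_means <- stats$mean
  if (is.null(region_sds)) region_sds <- stats$sd
  missing <- setdiff(schema$region, names(region_means))
  if (length(missing)) stop("region_means missing: ",
                            paste(missing, collapse = ", "))
  region_means <- region_means[schema$region]
  region_sds <- region_sds[schema$region]
  if (any(region_sds <= 0)) stop("region SDs must be positive")

  if (is.null(grid)) {
    grid <- event_grid(intersect(default_signal_regions(), schema$region))
  }
  unknown <- setdiff(grid$biomarkers, schema$region)
  if (length(unknown)) {
    stop("grid biomarkers not in schema: ", paste(unknown, collapse = ", "))
  }
  if (is.null(true_sequences)) {
    ord <- default_subtype_orders()
    ord <- lapply(ord, intersect, grid$biomarkers)
    true_sequences <- lapply(ord[seq_along(true_fractions)],
                             function(o) staged_sequence(grid, o))
  }
  for (s in true_sequences) {
    if (!is_valid_sequence(s, grid)) stop("invalid true sequence")
  }
  C <- length(true_sequences)
  true_fractions <- as.numeric(true_fractions)
  if (length(true_fractions) != C) stop("need one fraction per sequence")
  if (abs(sum(true_fractions) - 1) > 1e-12 || any(true_fractions < 0)) {
    stop("true_fractions must be non-negative and sum to 1")
  }
  if (is.null(pathology_mixing)) {
    pathology_mixing <- default_pathology_mixing(C)
  }
  if (ncol(pathology_mixing) != C) {
    stop("pathology_mixing needs one column per subtype")
  }
  if (!identical(stage_increment$dist, "poisson") &&
      !identical(stage_increment$dist, "fixed")) {
    stop("stage_increment$dist must be 'poisson' or 'fixed'")
  }
  if (identical(stage_increment$dist, "fixed") &&
      stage_increment$value < 0) {
    stop("stage increments must be non-negative")
  }
  if (identical(stage_increment$dist, "poisson") &&
      stage_increment$lambda < 0) {
    stop("stage increments must be non-negative")
  }

  # scalar covariate effects are fractions of the region mean
  expand <- function(x) {
    if (length(x) == 1L) x * region_means else x[schema$region]
  }
  structure(list(
    n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
    schema = schema, grid = grid,
    true_sequences = true_sequences, true_fractions = true_fractions,
    region_means = region_means, region_sds = region_sds,
    age_slope = expand(age_slope), sex_offset = expand(sex_offset),
    tiv_slope = if (length(tiv_slope) == 1L)
      tiv_slope * region_means / 1.45e6 else tiv_slope[schema$region],
    field_offset = expand(field_offset),
    manufacturer_offset = expand(manufacturer_offset),
    noise_sd = noise_sd,
    asymmetry = rep_len(asymmetry, C),
    pathology_mixing = pathology_mixing,
    followup_fraction = followup_fraction,
    n_followup_probs = n_followup_probs,
    stage_increment = stage_increment,
    followup_interval = followup_interval,
    seed = as.integer(seed),
    age_ref = 66, tiv_ref = 1.45e6
  ), class = "cohort_settings")
}

# Draw scan covariates for n subjects.
draw_covariates <- function(n, settings) {
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  data.frame(
    age = pmin(90, pmax(45, rnorm(n, settings$age_ref, 8))),
    sex = sex,
    tiv = pmax(9e5, rnorm(n, 1.40e6 + 1e5 * (sex == "M"), 1.1e5)),
    field_strength = sample(c("3T", "1.5T"), n, replace = TRUE,
                            prob = c(0.7, 0.3)),
    manufacturer = sample(c("Siemens", "GE"), n, replace = TRUE,
                          prob = c(0.6, 0.4)),
    stringsAsFactors = FALSE
  )
}

# Combined-region volumes from latent z and covariates; z is n x B over
# grid biomarkers (disease signal + noise); non-grid regions get noise only.
volumes_from_latent <- function(z_disease, noise, covs, settings) {
  schema <- settings$schema
  n <- nrow(covs)
  R <- nrow(schema)
  z <- noise                                 # n x R, z-unit noise all regions
  gi <- match(settings$grid$biomarkers, schema$region)
  z[, gi] <- z[, gi] + z_disease
  vol <- matrix(rep(settings$region_means, each = n), nrow = n) -
    z * matrix(rep(settings$region_sds, each = n), nrow = n)
  vol <- vol +
    outer(covs$age - settings$age_ref, settings$age_slope) +
    outer(as.numeric(covs$sex == "M"), settings$sex_offset) +
    outer(covs$tiv - settings$tiv_ref, settings$tiv_slope) +
    outer(as.numeric(covs$field_strength == "3T"), settings$field_offset) +
    outer(as.numeric(covs$manufacturer == "GE"),
          settings$manufacturer_offset)
  colnames(vol) <- schema$region
  pmax(vol, 1)
}

# Split combined volumes into left/right raw columns with per-scan
# asymmetry fraction a (vector length n); midline regions pass through.
split_hemispheres <- function(vol, schema, a) {
  out <- list()
  for (i in seq_len(nrow(schema))) {
    r <- schema$region[i]
    if (schema$paired[i]) {
      out[[paste0(r, "_L")]] <- vol[, r] * (1 - a) / 2
      out[[paste0(r, "_R")]] <- vol[, r] * (1 + a) / 2
    } else {
      out[[r]] <- vol[, r]
    }
  }
  as.data.frame(out)
}

#' Generate a synthetic baseline cohort with known ground truth
#'
#' Controls carry no atrophy signal (latent z = 0 plus noise). Each case is
#' assigned a latent subtype (sampled from the true fractions), a latent
#' stage (uniform on 0..N) and a pathology label (sampled conditional on
#' subtype); its latent z-scores are the subtype trajectory at that stage
#' plus Gaussian noise. Latent z is converted to volume as
#' control mean - z * control SD, covariate effects are added, and paired
#' regions are emitted as left/right columns.
#'
#' @param settings a [cohort_settings()].
#' @return List with `scans` (one row per scan: identifiers, covariates and
#'   raw per-hemisphere volumes) and `truth` (per-scan latent subtype,
#'   stage and pathology; `NA` subtype/stage for controls).
#' @export
generate_cohort <- function(settings) {
  stopifnot(inherits(settings, "cohort_settings"))
  with_seed(settings$seed, {
    schema <- settings$schema
    grid <- settings$grid
    N <- grid$n_events
    B <- length(grid$biomarkers)
    R <- nrow(schema)
    trajs <- lapply(settings$true_sequences, trajectory_matrix, grid)

    n_ctl <- settings$n_controls
    n_cas <- settings$n_cases
    covs_c <- draw_covariates(n_ctl, settings)
    covs_k <- draw_covariates(n_cas, settings)

    subtype <- sample.int(length(settings$true_fractions), n_cas,
                          replace = TRUE, prob = settings$true_fractions)
    stage <- sample.int(N + 1L, n_cas, replace = TRUE) - 1L
    pathology <- vapply(subtype, function(c) {
      sample(rownames(settings$pathology_mixing), 1L,
             prob = settings$pathology_mixing[, c])
    }, character(1))

    zd_ctl <- matrix(0, n_ctl, B)
    zd_cas <- t(vapply(seq_len(n_cas),
                       function(i) trajs[[subtype[i]]][, stage[i] + 1L],
                       numeric(B)))
    noise_c <- matrix(rnorm(n_ctl * R, 0, settings$noise_sd), n_ctl, R)
    noise_k <- matrix(rnorm(n_cas * R, 0, settings$noise_sd), n_cas, R)

    vol_c <- volumes_from_latent(zd_ctl, noise_c, covs_c, settings)
    vol_k <- volumes_from_latent(zd_cas, noise_k, covs_k, settings)

    a_cas <- settings$asymmetry[subtype]
    raw_c <- split_hemispheres(vol_c, schema, rep(0, n_ctl))
    raw_k <- split_hemispheres(vol_k, schema, a_cas)

    meta_c <- data.frame(
      subject_id = sprintf("ctl%03d", seq_len(n_ctl)),
      scan_id = sprintf("ctl%03d_v0", seq_len(n_ctl)),
      visit = 0L, group = "control", pathology = "none",
      covs_c, stringsAsFactors = FALSE)
    meta_k <- data.frame(
      subject_id = sprintf("cas%03d", seq_len(n_cas)),
      scan_id = sprintf("cas%03d_v0", seq_len(n_cas)),
      visit = 0L, group = "case", pathology = pathology,
      covs_k, stringsAsFactors = FALSE)

    scans <- rbind(cbind(meta_c, raw_c), cbind(meta_k, raw_k))
    rownames(scans) <- NULL
    truth <- data.frame(
      scan_id = scans$scan_id, subject_id = scans$subject_id,
      visit = 0L,
      subtype = c(rep(NA_integer_, n_ctl), subtype),
      stage = c(rep(NA_integer_, n_ctl), stage),
      pathology = scans$pathology, stringsAsFactors = FALSE)
    list(scans = scans, truth = truth)
  })
}

# One draw per subject from the stage-increment distribution (>= 0).
draw_increments <- function(n, spec) {
  switch(spec$dist,
         poisson = rpois(n, spec$lambda),
         fixed = rep.int(as.integer(spec$value), n),
         stop("unknown increment distribution"))
}

#' Generate follow-up scans for a synthetic cohort
#'
#' A seeded fraction of cases receives 1-3 follow-up visits. At each visit
#' the latent stage advances by a non-negative draw from the configured
#' increment distribution (capped at N), age advances by the follow-up
#' interval, and scanner covariates are held fixed (same scanner at
#' follow-up). Volumes are re-generated from the advanced latent z with
#' fresh measurement noise.
#'
#' @param cohort output of [generate_cohort()].
#' @param settings the same [cohort_settings()].
#' @param seed optional seed; defaults to `settings$seed + 1`.
#' @return List with `scans` and `truth` for the follow-up scans only (same
#'   columns as the baseline tables).
#' @export
generate_followups <- function(cohort, settings, seed = NULL) {
  stopifnot(inherits(settings, "cohort_settings"))
  seed <- seed %||% (settings$seed + 1L)
  with_seed(seed, {
    schema <- settings$schema
    grid <- settings$grid
    N <- grid$n_events
    B <- length(grid$biomarkers)
    R <- nrow(schema)
    trajs <- lapply(settings$true_sequences, trajectory_matrix, grid)

    tr <- cohort$truth
    base <- tr[!is.na(tr$subtype) & tr$visit == 0L, ]
    n_fu_subj <- round(settings$followup_fraction * nrow(base))
    if (n_fu_subj == 0L) {
      return(list(scans = cohort$scans[0, ], truth = tr[0, ]))
    }
    picked <- sort(sample.int(nrow(base), n_fu_subj))
    sc_all <- list()
    tr_all <- list()
    for (i in picked) {
      sid <- base$subject_id[i]
      row0 <- cohort$scans[cohort$scans$scan_id == base$scan_id[i], ]
      n_visits <- sample.int(length(settings$n_followup_probs), 1L,
                             prob = settings$n_followup_probs)
      stage_prev <- base$stage[i]
      for (v in seq_len(n_visits)) {
        inc <- draw_increments(1L, settings$stage_increment)
        stage_new <- min(N, stage_prev + inc)
        covs <- data.frame(
          age = row0$age + v * settings$followup_interval,
          sex = row0$sex, tiv = row0$tiv,
          field_strength = row0$field_strength,
          manufacturer = row0$manufacturer, stringsAsFactors = FALSE)
        zd <- matrix(trajs[[base$subtype[i]]][, stage_new + 1L], 1L, B)
        noise <- matrix(rnorm(R, 0, settings$noise_sd), 1L, R)
        vol <- volumes_from_latent(zd, noise, covs, settings)
        raw <- split_hemispheres(vol, schema,
                                 settings$asymmetry[base$subtype[i]])
        sc_all[[length(sc_all) + 1L]] <- cbind(
          data.frame(subject_id = sid,
                     scan_id = sprintf("%s_v%d", sid, v),
                     visit = v, group = "case",
                     pathology = base$pathology[i],
                     covs, stringsAsFactors = FALSE), raw)
        tr_all[[length(tr_all) + 1L]] <- data.frame(
          scan_id = sprintf("%s_v%d", sid, v), subject_id = sid,
          visit = v, subtype = base$subtype[i], stage = stage_new,
          pathology = base$pathology[i], stringsAsFactors = FALSE)
        stage_prev <- stage_new
      }
    }
    scans <- do.call(rbind, sc_all)
    rownames(scans) <- NULL
    list(scans = scans, truth = do.call(rbind, tr_all))
  })
}

#' Simulate a z-score cohort directly from the event-based model
#'
#' Draws each scan's subtype from the mixture fractions, its stage
#' uniformly on 0..N, and observes the subtype trajectory at that stage
#' plus independent Gaussian noise. This generates data exactly from the
#' model the fitting routines assume -- the clean setting for studying
#' sequence recovery and model selection, free of harmonization effects.
#'
#' @param grid an [event_grid()].
#' @param sequences list of true event sequences.
#' @param fractions mixture fractions (summing to 1).
#' @param n number of scans.
#' @param sigma noise SD in z-units (default 1).
#' @param seed integer seed.
#' @return List: `X` (n x biomarkers z-score matrix with scan ids),
#'   `subtype`, `stage` (ground truth vectors).
#' @export
simulate_zscore_cohort <- function(grid, sequences, fractions, n,
                                   sigma = 1, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  trajs <- lapply(sequences, trajectory_matrix, grid)
  N <- grid$n_events
  B <- length(grid$biomarkers)
  with_seed(seed, {
    subtype <- sample.int(length(fractions), n, replace = TRUE,
                          prob = fractions)
    stage <- sample.int(N + 1L, n, replace = TRUE) - 1L
    X <- t(vapply(seq_len(n),
                  function(i) trajs[[subtype[i]]][, stage[i] + 1L],
                  numeric(B))) +
      matrix(rnorm(n * B, 0, sigma), n, B)
    X <- matrix(X, n, B,
                dimnames = list(sprintf("sim%04d", seq_len(n)),
                                grid$biomarkers))
    list(X = X, subtype = subtype, stage = stage)
  })
}

#' Noise-free latent z-scores implied by the ground truth
#'
#' Returns, for every scan in a truth table, the exact trajectory z-score
#' of its latent subtype at its latent stage (0 for controls). Useful for
#' testing staging logic free of measurement noise.
#'
#' @param truth a truth table from [generate_cohort()] /
#'   [generate_followups()].
#' @param settings the [cohort_settings()] used to generate it.
#' @return Matrix scans x grid biomarkers with `scan_id` rownames.
#' @export
true_zscores <- function(truth, settings) {
  grid <- settings$grid
  trajs <- lapply(settings$true_sequences, trajectory_matrix, grid)
  B <- length(grid$biomarkers)
  out <- matrix(0, nrow(truth), B,
                dimnames = list(truth$scan_id, grid$biomarkers))
  for (i in seq_len(nrow(truth))) {
    if (!is.na(truth$subtype[i])) {
      out[i, ] <- trajs[[truth$subtype[i]]][, truth$stage[i] + 1L]
    }
  }
  out
}
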