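# Shared fixtures: small grids and the two-subtype recovery cohort
# (6 biomarkers x 2 thresholds, reversed orderings, fractions 0.6/0.4,
# sigma = 1) used across fitting, staging and validation tests.

six_region_grid <- function(thresholds = c(1, 2), z_max = 5) {
  event_grid(c("midbrain", "pons", "thalamus", "frontal_posterior",
               "parietal", "occipital"), thresholds, z_max)
}

reversed_pair <- function(grid) {
  B <- length(grid$biomarkers)
  list(staged_sequence(grid, seq_len(B)),
       staged_sequence(grid, rev(seq_len(B))))
}

recovery_settings <- function(seed, n_cases = 300L, n_controls = 252L,
                              noise_sd = 1, ...) {
  g <- six_region_grid()
  cohort_settings(n_controls = n_controls, n_cases = n_cases, grid = g,
                  true_sequences = reversed_pair(g),
                  true_fractions = c(0.6, 0.4),
                  noise_sd = noise_sd, seed = seed, ...)
}

# Generate, combine hemispheres, harmonize on controls and z-score the
# generator's grid biomarkers.
cohort_zscores <- function(settings, followups = FALSE) {
  co <- generate_cohort(settings)
  scans <- co$scans
  truth <- co$truth
  if (followups) {
    fu <- generate_followups(co, settings)
    scans <- rbind(scans, fu$scans)
    truth <- rbind(truth, fu$truth)
  }
  cmb <- combine_hemispheres(scans, settings$schema)
  hm <- fit_covariate_model(
    cmb[cmb$group == "control" & cmb$visit == 0L, ], settings$schema)
  adj <- apply_harmonization(cmb, hm)
  Z <- to_zscores(adj, hm, settings$grid$biomarkers)
  list(scans = scans, truth = truth, combined = cmb, harmonization = hm,
       adjusted = adj, Z = Z)
}

# Exhaustive-search reference: best single-sequence log-likelihood over
# all valid orderings, via the mixture likelihood with C = 1. Independent
# of the greedy optimizer's search path.
brute_force_best <- function(X, grid, sigma = 1) {
  best <- -Inf
  bs <- NULL
  for (s in all_valid_sequences(grid)) {
    ll <- mixture_loglik(X, subtype_model(list(s), 1, grid, sigma))
    if (ll > best) {
      best <- ll
      bs <- s
    }
  }
  list(sequence = bs, loglik = best)
}

# Random small instance: a random grid with at most `n_max` events and a
# z-score matrix drawn from a random sequence plus noise.
random_instance <- function(n_max = 5L, n_subjects = 15L) {
  repeat {
    B <- sample(1:3, 1L)
    counts <- sample(1:3, B, replace = TRUE)
    if (sum(counts) <= n_max) break
  }
  grid <- event_grid(paste0("b", seq_len(B)),
                     lapply(counts, function(k) seq_len(k)),
                     z_max = 4)
  N <- grid$n_events
  s <- staged_sequence(grid, sample(B))
  traj <- trajectory_matrix(s, grid)
  stages <- sample(0:N, n_subjects, replace = TRUE)
  X <- t(traj[, stages + 1L, drop = FALSE]) +
    matrix(rnorm(n_subjects * B), n_subjects, B)
  list(grid = grid, X = matrix(X, n_subjects, B))
}
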