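# Event grids, piecewise-linear trajectories and stage-marginal
# likelihoods.

test_that("trajectories interpolate linearly between event anchors", {
  # biomarker a: single threshold {1}, z_max 3; filler biomarker b brings
  # the grid to N = 4 events
  grid <- event_grid(c("a", "b"), thresholds = list(1, c(1, 2, 3)),
                     z_max = c(3, 4))
  # a's event at position 2
  ev <- grid$events
  a1 <- which(ev$biomarker == 1L)
  b <- which(ev$biomarker == 2L)
  s <- c(b[1L], a1, b[2L], b[3L])
  expect_equal(trajectory_value(s, grid, "a", 0), 0)
  expect_equal(trajectory_value(s, grid, "a", 2), 1)
  # between (2, 1) and (4, 3): value at t = 3 is 1 + (3-1)*(3-2)/(4-2) = 2
  expect_equal(trajectory_value(s, grid, "a", 3), 2)
  expect_equal(trajectory_value(s, grid, "a", 4), 3)
  # rows are non-decreasing
  tm <- trajectory_matrix(s, grid)
  expect_true(all(diff(t(tm)) >= 0))
})

test_that("a biomarker whose last event sits at position N is capped at its final threshold", {
  grid <- event_grid(c("a", "b"), thresholds = list(1, 1), z_max = 5)
  s <- c(2L, 1L)                        # a's single event at position N = 2
  expect_equal(trajectory_value(s, grid, "a", 2), 1)
  # b's event at position 1 rises to z_max at N
  expect_equal(trajectory_value(s, grid, "b", 2), 5)
  expect_error(trajectory_value(s, grid, "a", 3), "stage")
})

test_that("stage likelihood vector matches per-stage Gaussian products", {
  # 2 biomarkers, 1 threshold each, z_max = 1, sequence (b1, b2)
  grid <- event_grid(c("x", "y"), thresholds = 1, z_max = 1)
  s <- c(1L, 2L)
  x <- c(1, 0)
  # trajectories: x -> (0, 1, 1), y -> (0, 0.5, 1)
  expected <- c(dnorm(1, 0, 1) * dnorm(0, 0, 1),
                dnorm(1, 1, 1) * dnorm(0, 0.5, 1),
                dnorm(1, 1, 1) * dnorm(0, 1, 1))
  expect_equal(stage_likelihood_vector(x, s, grid), expected,
               tolerance = 1e-10)
  # consistency: data at the stage-k trajectory peaks at k for tiny sigma
  for (k in 0:2) {
    v <- stage_likelihood_vector(trajectory_matrix(s, grid)[, k + 1L],
                                 s, grid, sigma = 0.01)
    expect_equal(which.max(v) - 1L, k)
  }
  # flat-likelihood limit: huge sigma gives near-constant vector
  v <- stage_likelihood_vector(x, s, grid, sigma = 1e6)
  expect_lt(diff(range(v)) / mean(v), 1e-9)
  expect_error(stage_likelihood_vector(c(1, 0, 0), s, grid), "entry")
})

test_that("subject log-likelihood equals the closed two-stage form and posteriors normalize", {
  grid <- event_grid("x", thresholds = 1, z_max = 1)
  res <- subject_loglik(0, 1L, grid, sigma = 1)
  expect_equal(res$loglik, log(0.5 * (dnorm(0) + dnorm(0, 1, 1))),
               tolerance = 1e-12)
  # posterior sums to 1 for random inputs
  set.seed(7)
  g2 <- six_region_grid()
  s <- staged_sequence(g2, 1:6)
  for (i in 1:20) {
    r <- subject_loglik(rnorm(6, 1, 2), s, g2)
    expect_equal(sum(r$stage_posterior), 1, tolerance = 1e-12)
  }
})

test_that("mixture log-likelihood reduces to C=1 sums and matches brute force", {
  set.seed(11)
  grid <- event_grid(c("a", "b"), thresholds = 1, z_max = 2)
  s1 <- c(1L, 2L)
  s2 <- c(2L, 1L)
  X <- matrix(rnorm(6, 1), 3, 2)
  m1 <- subtype_model(list(s1), 1, grid)
  expect_equal(mixture_loglik(X, m1),
               sum(vapply(1:3, function(i)
                 subject_loglik(X[i, ], s1, grid)$loglik, numeric(1))))
  # a zero-weight component is ignored
  m10 <- subtype_model(list(s1, s2), c(1, 0), grid)
  expect_equal(mixture_loglik(X, m10), mixture_loglik(X, m1))
  # brute-force: explicit exponentials over 2 subjects, tiny grid
  m <- subtype_model(list(s1, s2), c(0.3, 0.7), grid)
  X2 <- X[1:2, ]
  manual <- sum(vapply(1:2, function(i) {
    log(0.3 * exp(subject_loglik(X2[i, ], s1, grid)$loglik) +
          0.7 * exp(subject_loglik(X2[i, ], s2, grid)$loglik))
  }, numeric(1)))
  expect_equal(mixture_loglik(X2, m), manual, tolerance = 1e-12)
  # invariant under permuting subtypes together with fractions
  mp <- subtype_model(list(s2, s1), c(0.7, 0.3), grid)
  expect_equal(mixture_loglik(X2, mp), mixture_loglik(X2, m))
})

test_that("likelihoods are invariant under consistent biomarker relabeling", {
  set.seed(3)
  grid <- event_grid(c("a", "b", "c"), thresholds = list(1, c(1, 2), 1),
                     z_max = 3)
  s <- staged_sequence(grid, c(2, 1, 3))
  x <- rnorm(3, 1)
  perm <- c(3L, 1L, 2L)                 # new index of old biomarker
  grid_p <- event_grid(grid$biomarkers[order(perm)],
                       grid$thresholds[order(perm)],
                       grid$z_max[order(perm)])
  ev <- grid$events
  evp <- grid_p$events
  s_p <- vapply(s, function(e)
    which(evp$biomarker == perm[ev$biomarker[e]] &
            evp$level == ev$level[e]), integer(1))
  x_p <- x[order(perm)]
  expect_equal(subject_loglik(x_p, s_p, grid_p)$loglik,
               subject_loglik(x, s, grid)$loglik, tolerance = 1e-12)
})

test_that("noise-free data from a known sequence is maximized by that sequence", {
  grid <- event_grid(c("a", "b"), thresholds = list(c(1, 2), c(1, 2)),
                     z_max = 3)
  s_true <- staged_sequence(grid, c(1, 2))
  traj <- trajectory_matrix(s_true, grid)
  X <- t(traj)                          # one subject at every stage 0..N
  ll_true <- mixture_loglik(X, subtype_model(list(s_true), 1, grid))
  for (s in all_valid_sequences(grid)) {
    expect_lte(mixture_loglik(X, subtype_model(list(s), 1, grid)),
               ll_true + 1e-9)
  }
})

test_that("invalid grids and sequences are rejected", {
  expect_error(event_grid("a", thresholds = c(2, 1)), "increasing")
  expect_error(event_grid("a", thresholds = c(1, 2), z_max = 1.5), "z_max")
  grid <- event_grid("a", thresholds = c(1, 2))
  expect_error(trajectory_matrix(c(2L, 1L), grid), "invalid")
  expect_error(subtype_model(list(c(1L, 2L)), 0.5, grid), "sum to 1")
})
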