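#' Event grid: z-score thresholds per biomarker
#'
#' An event grid defines, for each biomarker, an increasing set of z-score
#' thresholds. Each threshold crossing is one *event*; the model orders all
#' N = sum of per-biomarker thresholds events into a sequence. `z_max` is
#' the asymptotic z-score a biomarker approaches at the final stage when its
#' last event occurs before the end of the sequence.
#'
#' @param biomarkers character vector of biomarker names.
#' @param thresholds either a single numeric vector of increasing thresholds
#'   applied to every biomarker (default `c(1, 2, 3)`), or a named list with
#'   one increasing numeric vector per biomarker.
#' @param z_max numeric scalar or per-biomarker vector; must be at least the
#'   last threshold of each biomarker (default 5).
#' @return Object of class `event_grid` with fields `biomarkers`,
#'   `thresholds` (list), `z_max` (vector), `events` (data frame with one
#'   row per event: `biomarker` index, `level` threshold index, `z` value),
#'   and `n_events`.
#' @export
event_grid <- function(biomarkers, thresholds = c(1, 2, 3), z_max = 5) {
  stopifnot(is.character(biomarkers), length(biomarkers) >= 1L)
  if (anyDuplicated(biomarkers)) stop("biomarker names must be unique")
  B <- length(biomarkers)
  if (!is.list(thresholds)) thresholds <- rep(list(as.numeric(thresholds)), B)
  if (length(thresholds) != B) stop("need one threshold vector per biomarker")
  names(thresholds) <- biomarkers
  for (th in thresholds) {
    if (length(th) < 1L || any(diff(th) <= 0)) {
      stop("thresholds must be non-empty and strictly increasing")
    }
  }
  z_max <- rep_len(as.numeric(z_max), B)
  last <- vapply(thresholds, function(t) t[length(t)], numeric(1))
  if (any(z_max < last)) stop("z_max must be >= the last threshold")
  events <- data.frame(
    biomarker = rep.int(seq_len(B), lengths(thresholds)),
    level = unlist(lapply(thresholds, seq_along), use.names = FALSE),
    z = unlist(thresholds, use.names = FALSE)
  )
  structure(list(biomarkers = biomarkers, thresholds = thresholds,
                 z_max = z_max, events = events, n_events = nrow(events)),
            class = "event_grid")
}

#' @export
print.event_grid <- function(x, ...) {
  cat("event grid:", length(x$biomarkers), "biomarkers,",
      x$n_events, "events\n")
  invisible(x)
}

# TRUE iff `s` is a permutation of all event ids with within-biomarker
# thresholds in increasing order.
is_valid_sequence <- function(s, grid) {
  N <- grid$n_events
  if (length(s) != N || !setequal(s, seq_len(N))) return(FALSE)
  ev <- grid$events
  for (b in unique(ev$biomarker)) {
    ids <- which(ev$biomarker == b)
    pos <- match(ids, s)                # ids are already in level order
    if (is.unsorted(pos, strictly = TRUE)) return(FALSE)
  }
  TRUE
}

# Random valid sequence: random positions, then within each biomarker the
# occupied positions are reassigned in increasing threshold order.
random_sequence <- function(grid) {
  N <- grid$n_events
  s <- sample.int(N)
  ev <- grid$events
  for (b in unique(ev$biomarker)) {
    ids <- which(ev$biomarker == b)
    pos <- sort(match(ids, s))
    s[pos] <- ids
  }
  s
}

#' Expected biomarker trajectories of an event sequence
#'
#' Under a sequence S over an event grid, biomarker i's expected z-score is
#' the piecewise-linear curve through (stage 0, z = 0) and
#' (position of event (i,j), threshold z_ij), reaching `z_max_i` at stage N
#' when the biomarker's last event occurs before position N; when its last
#' event occupies position N the curve is capped at that final threshold.
#'
#' @param s integer vector: event id at positions 1..N.
#' @param grid an [event_grid()].
#' @return A `B x (N+1)` matrix of expected z-scores at integer stages
#'   `0..N` (columns), non-decreasing along each row.
#' @export
trajectory_matrix <- function(s, grid) {
  N <- grid$n_events
  if (!is_valid_sequence(s, grid)) stop("invalid event sequence")
  ev <- grid$events
  B <- length(grid$biomarkers)
  out <- matrix(0, nrow = B, ncol = N + 1L,
                dimnames = list(grid$biomarkers, NULL))
  pos_of <- match(seq_len(N), s)        # event id -> position
  for (b in seq_len(B)) {
    ids <- which(ev$biomarker == b)
    xs <- c(0, pos_of[ids])
    ys <- c(0, ev$z[ids])
    if (xs[length(xs)] < N) {
      xs <- c(xs, N)
      ys <- c(ys, grid$z_max[b])
    }
    out[b, ] <- approx(xs, ys, xout = 0:N, rule = 2)$y
  }
  out
}

#' Expected z-score of one biomarker at one stage
#'
#' Scalar convenience wrapper around [trajectory_matrix()].
#'
#' @inheritParams trajectory_matrix
#' @param biomarker biomarker index or name.
#' @param stage integer stage in `0..N`.
#' @return Expected z-score (numeric scalar).
#' @export
trajectory_value <- function(s, grid, biomarker, stage) {
  N <- grid$n_events
  if (!is.numeric(stage) || stage != round(stage) || stage < 0 || stage > N) {
    stop("stage must be an integer in [0, ", N, "]")
  }
  if (is.character(biomarker)) {
    biomarker <- match(biomarker, grid$biomarkers)
    if (is.na(biomarker)) stop("unknown biomarker")
  }
  unname(trajectory_matrix(s, grid)[biomarker, stage + 1L])
}

# Per-subject, per-stage Gaussian log-likelihood matrix.
# X: n x B z-score matrix; traj: B x (K+1) trajectory matrix; sigma: length-B.
# Returns n x (K+1): entry (s, k) = sum_i log N(x_si; traj[i,k], sigma_i).
stage_loglik_matrix <- function(X, traj, sigma) {
  X <- as.matrix(X)
  B <- nrow(traj)
  if (ncol(X) != B) stop("z-score matrix has ", ncol(X),
                         " biomarkers; model expects ", B)
  if (any(!is.finite(X))) stop("z-scores must be finite")
  sigma <- rep_len(sigma, B)
  if (any(sigma <= 0)) stop("noise scales must be positive")
  w <- 1 / sigma^2
  const <- -sum(log(sigma)) - B * 0.5 * log(2 * pi)
  q1 <- drop((X^2) %*% w)               # n
  q2 <- drop(w %*% traj^2)              # K+1
  cross <- (X * rep(w, each = nrow(X))) %*% traj   # n x (K+1)
  -0.5 * (outer(q1, q2, "+") - 2 * cross) + const
}

#' Per-stage likelihood of one scan under one sequence
#'
#' Entry k (k = 0..N) is the product over biomarkers of Gaussian densities
#' of the observed z-scores around the sequence's expected trajectory at
#' stage k. Computed in log-space internally.
#'
#' @param x numeric z-score vector, one entry per grid biomarker.
#' @param s event sequence.
#' @param grid an [event_grid()].
#' @param sigma per-biomarker noise SD in z-units (recycled; default 1).
#' @param log return log-likelihoods instead of likelihoods?
#' @return Numeric vector of length `N + 1` (stages 0..N).
#' @export
stage_likelihood_vector <- function(x, s, grid, sigma = 1, log = FALSE) {
  if (length(x) != length(grid$biomarkers)) {
    stop("x must have one entry per biomarker")
  }
  ll <- stage_loglik_matrix(matrix(x, nrow = 1L), trajectory_matrix(s, grid),
                            sigma)[1L, ]
  if (log) ll else exp(ll)
}

#' Stage-marginal log-likelihood of one scan under one sequence
#'
#' The subject-level model places a uniform prior over the N + 1 stages, so
#' the marginal likelihood is the mean of the per-stage likelihoods. The
#' normalized per-stage vector is the stage posterior.
#'
#' @inheritParams stage_likelihood_vector
#' @return List with `loglik` (scalar) and `stage_posterior`
#'   (length `N + 1`, sums to 1).
#' @export
subject_loglik <- function(x, s, grid, sigma = 1) {
  ll <- stage_likelihood_vector(x, s, grid, sigma, log = TRUE)
  lse <- logsumexp(ll)
  list(loglik = lse - log(length(ll)),
       stage_posterior = exp(ll - lse))
}

# Vectorized stage-marginal log-likelihood for all rows of X under one
# trajectory matrix. Returns length-n vector.
subject_logliks <- function(X, traj, sigma) {
  ll <- stage_loglik_matrix(X, traj, sigma)
  row_logsumexp(ll) - log(ncol(ll))
}

#' Construct a subtype mixture model
#'
#' Bundles C event sequences with mixture fractions and a noise model into
#' the object used for likelihood evaluation, staging and sampling.
#'
#' @param sequences list of event sequences over `grid`.
#' @param fractions mixture fractions, summing to 1.
#' @param grid an [event_grid()].
#' @param sigma per-biomarker noise SD (default 1).
#' @param mcmc optional MCMC sample store (see [mcmc_sample()]).
#' @return Object of class `subtype_model`.
#' @export
subtype_model <- function(sequences, fractions, grid, sigma = 1,
                          mcmc = NULL) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  C <- length(sequences)
  fractions <- as.numeric(fractions)
  if (length(fractions) != C) stop("need one fraction per sequence")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be non-negative and sum to 1")
  }
  for (s in sequences) {
    if (!is_valid_sequence(s, grid)) stop("invalid event sequence in model")
  }
  sigma <- rep_len(as.numeric(sigma), length(grid$biomarkers))
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(list(sequences = sequences, fractions = fractions,
                 grid = grid, sigma = sigma,
                 trajectories = lapply(sequences, trajectory_matrix, grid),
                 mcmc = mcmc),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype mixture model: C =", length(x$sequences),
      "subtypes over", x$grid$n_events, "events\n")
  cat("fractions:", paste(signif(x$fractions, 3), collapse = ", "), "\n")
  invisible(x)
}

# n x C matrix of stage-marginal log-likelihoods, one column per subtype.
subtype_loglik_matrix <- function(X, model) {
  X <- as.matrix(X)
  vapply(model$trajectories,
         function(tr) subject_logliks(X, tr, model$sigma),
         numeric(nrow(X)))
}

#' Total mixture log-likelihood of a z-score matrix
#'
#' Sum over scans of the log of the fraction-weighted mixture of each
#' subtype's stage-marginal likelihood; evaluated stably in log-space.
#'
#' @param X numeric matrix of z-scores, scans x biomarkers (columns in grid
#'   order).
#' @param model a [subtype_model()].
#' @return Total log-likelihood (scalar).
#' @export
mixture_loglik <- function(X, model) {
  f <- model$fractions
  if (abs(sum(f) - 1) > 1e-8) stop("mixture fractions must sum to 1")
  ll <- subtype_loglik_matrix(X, model)
  lw <- sweep(ll, 2L, ifelse(f > 0, log(f), -Inf), "+")
  sum(row_logsumexp(matrix(lw, nrow = nrow(ll))))
}
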