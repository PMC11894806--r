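# Fitting the subtype mixture: greedy sequence optimization with random
# restarts, hierarchical cluster splitting to grow the number of subtypes,
# EM refinement, Metropolis-Hastings uncertainty sampling, and K-fold
# cross-validated model selection via CVIC.

#' Fit settings
#'
#' @param n_starts random starting sequences for greedy optimization
#'   (default 25).
#' @param max_passes maximum greedy passes per start (default 50).
#' @param em_max_iter,em_tol EM iteration cap (default 100) and relative
#'   log-likelihood convergence tolerance (default 1e-6).
#' @param mcmc_iter MCMC iterations (default 1e5).
#' @param burnin_frac fraction of iterations discarded as burn-in
#'   (default 0.1).
#' @param n_split_attempts random bisections tried per parent cluster when
#'   growing the model (default 4; with fewer attempts the post-split EM
#'   occasionally settles in a poor symmetric optimum).
#' @param seed integer seed controlling every stochastic step.
#' @return Object of class `fit_settings`.
#' @export
fit_settings <- function(n_starts = 25L, max_passes = 50L,
                         em_max_iter = 100L, em_tol = 1e-6,
                         mcmc_iter = 1e5, burnin_frac = 0.1,
                         n_split_attempts = 4L, seed = 1L) {
  stopifnot(n_starts >= 1L, max_passes >= 1L, em_max_iter >= 1L,
            em_tol > 0, mcmc_iter >= 1L, burnin_frac >= 0,
            burnin_frac < 1, n_split_attempts >= 1L)
  structure(list(n_starts = as.integer(n_starts),
                 max_passes = as.integer(max_passes),
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 mcmc_iter = as.integer(mcmc_iter),
                 burnin_frac = burnin_frac,
                 n_split_attempts = as.integer(n_split_attempts),
                 seed = as.integer(seed)),
            class = "fit_settings")
}

# Precomputed per-dataset quantities for fast repeated likelihood
# evaluation under different trajectories.
likelihood_workspace <- function(X, sigma) {
  X <- as.matrix(X)
  B <- ncol(X)
  sigma <- rep_len(sigma, B)
  w <- 1 / sigma^2
  list(X = X, n = nrow(X), B = B, w = w,
       Xw = X * rep(w, each = nrow(X)),
       q1 = drop((X^2) %*% w),
       const = -sum(log(sigma)) - B * 0.5 * log(2 * pi))
}

# Stage-marginal log-likelihood per subject for one trajectory matrix.
ws_subject_logliks <- function(ws, traj) {
  K1 <- ncol(traj)
  q2 <- drop(ws$w %*% traj^2)
  ll <- -0.5 * (outer(ws$q1, q2, "+") - 2 * (ws$Xw %*% traj)) + ws$const
  row_logsumexp(ll) - log(K1)
}

# Weighted objective of a sequence.
ws_objective <- function(ws, s, grid, weights) {
  sum(weights * ws_subject_logliks(ws, trajectory_matrix(s, grid)))
}

#' Enumerate all valid event sequences
#'
#' All orderings of the grid's events that respect increasing threshold
#' order within each biomarker. Feasible only for small grids (N <= ~8);
#' used as the exhaustive reference for the greedy optimizer.
#'
#' @param grid an [event_grid()].
#' @return List of integer sequences.
#' @export
all_valid_sequences <- function(grid) {
  N <- grid$n_events
  ev <- grid$events
  if (N > 10L) stop("exhaustive enumeration is limited to N <= 10")
  # event e is placeable once its lower-threshold sibling is placed
  prev <- integer(N)
  for (e in seq_len(N)) {
    sib <- which(ev$biomarker == ev$biomarker[e] &
                   ev$level == ev$level[e] - 1L)
    prev[e] <- if (length(sib)) sib else 0L
  }
  out <- vector("list", 0L)
  recurse <- function(placed, used) {
    if (length(placed) == N) {
      out[[length(out) + 1L]] <<- placed
      return(invisible())
    }
    for (e in seq_len(N)) {
      if (!used[e] && (prev[e] == 0L || used[prev[e]])) {
        used[e] <- TRUE
        recurse(c(placed, e), used)
        used[e] <- FALSE
      }
    }
  }
  recurse(integer(0), logical(N))
  out
}

# Valid insertion positions for event e into sequence `rest` (length N-1):
# strictly after its lower-threshold sibling and strictly before its
# higher-threshold sibling. Returns insertion indices 1..N.
valid_insertions <- function(e, rest, grid) {
  ev <- grid$events
  b <- ev$biomarker[e]; lev <- ev$level[e]
  lo <- 1L
  hi <- length(rest) + 1L
  sib_lo <- which(ev$biomarker == b & ev$level == lev - 1L)
  sib_hi <- which(ev$biomarker == b & ev$level == lev + 1L)
  if (length(sib_lo)) lo <- match(sib_lo, rest) + 1L
  if (length(sib_hi)) hi <- match(sib_hi, rest)
  if (lo > hi) integer(0) else lo:hi
}

# One greedy run from a given starting sequence. Each pass removes every
# event in turn and reinserts it at the valid position with the highest
# weighted log-likelihood (first-encountered maximum; the event stays put
# on ties with its current position). Stops when a pass yields no strict
# improvement.
greedy_from <- function(ws, s, grid, weights, max_passes) {
  obj <- ws_objective(ws, s, grid, weights)
  N <- grid$n_events
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (e in seq_len(N)) {
      cur_pos <- match(e, s)
      rest <- s[-cur_pos]
      cand <- valid_insertions(e, rest, grid)
      best_obj <- obj
      best_s <- s
      for (p in cand) {
        s2 <- append(rest, e, after = p - 1L)
        if (identical(s2, s)) next
        o2 <- ws_objective(ws, s2, grid, weights)
        if (o2 > best_obj) {
          best_obj <- o2
          best_s <- s2
        }
      }
      if (best_obj > obj) {
        s <- best_s
        obj <- best_obj
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(sequence = s, loglik = obj)
}

#' Greedy event-sequence optimization with random restarts
#'
#' Maximizes the (optionally responsibility-weighted) sum of subject
#' stage-marginal log-likelihoods over valid event orderings by greedy
#' coordinate ascent: from a random valid sequence, repeatedly remove each
#' event and reinsert it at the valid position that maximizes the
#' objective, until a full pass makes no change; the best result over
#' `n_starts` restarts is returned. Deterministic given the seed.
#'
#' @param X z-score matrix, scans x biomarkers (grid order).
#' @param grid an [event_grid()].
#' @param sigma per-biomarker noise SD (default 1).
#' @param weights per-scan weights in `[0, 1]` (default 1).
#' @param settings a [fit_settings()]; `n_starts`, `max_passes` and `seed`
#'   are used.
#' @param init optional starting sequence; when given, a single greedy run
#'   starts there (no random restarts).
#' @return List with `sequence` and `loglik` (the weighted objective).
#' @export
optimize_sequence <- function(X, grid, sigma = 1, weights = NULL,
                              settings = fit_settings(), init = NULL) {
  if (grid$n_events < 1L) stop("grid has no events")
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("X is empty")
  weights <- weights %||% rep(1, nrow(X))
  if (length(weights) != nrow(X) || any(weights < 0)) {
    stop("weights must be a non-negative per-scan vector")
  }
  ws <- likelihood_workspace(X, sigma)
  if (!is.null(init)) {
    return(greedy_from(ws, init, grid, weights, settings$max_passes))
  }
  with_seed(settings$seed, {
    best <- NULL
    for (r in seq_len(settings$n_starts)) {
      res <- greedy_from(ws, random_sequence(grid), grid, weights,
                         settings$max_passes)
      if (is.null(best) || res$loglik > best$loglik) best <- res
    }
    best
  })
}

# EM refinement of a C-cluster model. Returns list(sequences, fractions,
# loglik, responsibilities, n_iter).
em_refine <- function(ws, sequences, fractions, grid, settings) {
  C <- length(sequences)
  n <- ws$n
  ll_cols <- vapply(sequences, function(s)
    ws_subject_logliks(ws, trajectory_matrix(s, grid)), numeric(n))
  ll_cols <- matrix(ll_cols, nrow = n)
  total <- -Inf
  r <- NULL
  for (iter in seq_len(settings$em_max_iter)) {
    lw <- sweep(ll_cols, 2L, ifelse(fractions > 0, log(fractions), -Inf),
                "+")
    lse <- row_logsumexp(lw)
    new_total <- sum(lse)
    r <- exp(lw - lse)
    # guard: an emptied cluster is re-seeded from the worst-fit subjects
    sizes <- colSums(r)
    for (c in which(sizes < 1e-8)) {
      k <- max(2L, ceiling(n / (4L * C)))
      worst <- order(lse)[seq_len(k)]
      r[worst, ] <- 0
      r[worst, c] <- 1
      message("EM: re-seeding empty cluster ", c, " from ", k,
              " worst-fit subjects")
    }
    if (is.finite(total) &&
        abs(new_total - total) <= settings$em_tol * abs(total)) {
      total <- new_total
      break
    }
    total <- new_total
    fractions <- colSums(r) / sum(r)
    for (c in seq_len(C)) {
      res <- greedy_from(ws, sequences[[c]], grid, r[, c],
                         settings$max_passes)
      sequences[[c]] <- res$sequence
      ll_cols[, c] <- ws_subject_logliks(
        ws, trajectory_matrix(res$sequence, grid))
    }
  }
  list(sequences = sequences, fractions = fractions, loglik = total,
       responsibilities = r, n_iter = iter)
}

#' Fit a C-subtype mixture of event sequences
#'
#' For C = 1 this is greedy sequence optimization with unit weights. For
#' C > 1 the model is grown hierarchically: a (C-1)-subtype model is fitted
#' first, each of its clusters is split by random bisection of its
#' maximum-likelihood members (each half refitted as a sequence), the best
#' split by post-EM log-likelihood is kept, and a final joint EM over all
#' C clusters is run to convergence.
#'
#' @inheritParams optimize_sequence
#' @param C number of subtypes.
#' @return A [subtype_model()] with an extra `fit` element recording the
#'   training log-likelihood, responsibilities and settings.
#' @export
fit_subtypes <- function(X, grid, sigma = 1, C = 1L,
                         settings = fit_settings()) {
  path <- fit_subtypes_path(X, grid, sigma, C_max = C, settings = settings)
  path[[C]]
}

#' Fit mixtures for every C from 1 to C_max
#'
#' Runs the hierarchical growth once, returning the whole path of models;
#' cheaper than separate [fit_subtypes()] calls when several C are needed
#' (as in cross-validation).
#'
#' @inheritParams fit_subtypes
#' @param C_max largest number of subtypes to fit.
#' @return List of [subtype_model()]s, element C being the C-subtype fit.
#' @export
fit_subtypes_path <- function(X, grid, sigma = 1, C_max = 1L,
                              settings = fit_settings()) {
  stopifnot(C_max >= 1L)
  X <- as.matrix(X)
  ws <- likelihood_workspace(X, sigma)
  n <- nrow(X)
  models <- vector("list", C_max)

  res1 <- optimize_sequence(X, grid, sigma, settings = settings)
  m <- subtype_model(list(res1$sequence), 1, grid, sigma)
  m$fit <- list(loglik = res1$loglik,
                responsibilities = matrix(1, n, 1L),
                settings = settings)
  models[[1L]] <- m

  if (C_max == 1L) return(models)

  sub_settings <- settings
  sub_settings$n_starts <- max(1L, ceiling(settings$n_starts / 5))

  for (C in 2L:C_max) {
    parent <- models[[C - 1L]]
    hard <- max.col(parent$fit$responsibilities, ties.method = "first")
    best <- NULL
    attempt_seed <- settings$seed + 1000L * C
    for (c in seq_len(C - 1L)) {
      members <- which(hard == c)
      if (length(members) < 4L) next
      for (a in seq_len(settings$n_split_attempts)) {
        halves <- with_seed(attempt_seed + 10L * c + a, {
          idx <- sample(members)
          split(idx, rep(1:2, length.out = length(idx)))
        })
        sub_settings$seed <- attempt_seed + 10L * c + a
        new_seqs <- lapply(halves, function(idx) {
          optimize_sequence(X[idx, , drop = FALSE], grid, sigma,
                            settings = sub_settings)$sequence
        })
        seqs <- c(parent$sequences[-c], new_seqs)
        fracs <- c(parent$fractions[-c], rep(parent$fractions[c] / 2, 2L))
        cand <- em_refine(ws, seqs, fracs, grid, settings)
        if (is.null(best) || cand$loglik > best$loglik) best <- cand
      }
    }
    if (is.null(best)) {
      stop("no cluster of the ", C - 1L, "-subtype model is large enough",
           " to split")
    }
    m <- subtype_model(best$sequences, best$fractions, grid, sigma)
    m$fit <- list(loglik = best$loglik,
                  responsibilities = best$responsibilities,
                  settings = settings)
    models[[C]] <- m
  }
  models
}

#' Metropolis-Hastings sampling of sequence and fraction uncertainty
#'
#' From a fitted model, each iteration either relocates one random event of
#' one random subtype to a random valid position (probability 0.9) or
#' jitters the mixture fractions with a Gaussian step on the simplex
#' (probability 0.1, SD 0.01, renormalized; proposals leaving the simplex
#' are rejected). Proposals are accepted with probability
#' min(1, exp(delta log-likelihood)). Post-burn-in samples yield the
#' positional variance diagram (PVD) of each subtype: the matrix of
#' posterior probabilities that event e occupies position p.
#'
#' @param model a fitted [subtype_model()].
#' @param X z-score matrix the model was fitted to.
#' @param settings a [fit_settings()]; `mcmc_iter`, `burnin_frac`, `seed`.
#' @param trace also record every proposal (state, log-likelihoods,
#'   accepted flag) for auditing the acceptance computation?
#' @return The model with an `mcmc` element: `sequences` (list per kept
#'   sample of C x N position-of-event matrices stored as integer event
#'   orders), `fractions` (samples x C), `loglik`, `acceptance_rate`, and
#'   `pvd` (list of N x N matrices, rows = events, columns = positions);
#'   with `trace = TRUE` also `trace`, a list of per-iteration proposals.
#' @export
mcmc_sample <- function(model, X, settings = fit_settings(),
                        trace = FALSE) {
  X <- as.matrix(X)
  ws <- likelihood_workspace(X, model$sigma)
  grid <- model$grid
  N <- grid$n_events
  C <- length(model$sequences)
  n_iter <- settings$mcmc_iter
  burn <- floor(settings$burnin_frac * n_iter)
  if (n_iter - burn < 1L) stop("no retained samples after burn-in")

  seqs <- model$sequences
  fracs <- model$fractions
  ll_cols <- vapply(seqs, function(s)
    ws_subject_logliks(ws, trajectory_matrix(s, grid)), numeric(ws$n))
  ll_cols <- matrix(ll_cols, nrow = ws$n)
  total_ll <- function(llc, f) {
    sum(row_logsumexp(sweep(llc, 2L, ifelse(f > 0, log(f), -Inf), "+")))
  }
  cur <- total_ll(ll_cols, fracs)

  n_keep <- n_iter - burn
  keep_seq <- vector("list", n_keep)
  keep_frac <- matrix(NA_real_, n_keep, C)
  keep_ll <- numeric(n_keep)
  accepted <- 0L
  trace_log <- if (trace) vector("list", n_iter) else NULL

  with_seed(settings$seed, {
    for (it in seq_len(n_iter)) {
      if (runif(1) < 0.9) {
        c <- sample.int(C, 1L)
        e <- sample.int(N, 1L)
        s <- seqs[[c]]
        rest <- s[-match(e, s)]
        cand <- valid_insertions(e, rest, grid)
        p <- cand[sample.int(length(cand), 1L)]
        s2 <- append(rest, e, after = p - 1L)
        new_col <- ws_subject_logliks(ws, trajectory_matrix(s2, grid))
        llc2 <- ll_cols
        llc2[, c] <- new_col
        prop <- total_ll(llc2, fracs)
        acc <- log(runif(1)) < prop - cur
        if (trace) {
          trace_log[[it]] <- list(move = "sequence", subtype = c,
                                  sequences = seqs, proposal = s2,
                                  fractions = fracs,
                                  cur_loglik = cur, prop_loglik = prop,
                                  accepted = acc)
        }
        if (acc) {
          seqs[[c]] <- s2
          ll_cols <- llc2
          cur <- prop
          accepted <- accepted + 1L
        }
      } else {
        f2 <- fracs + rnorm(C, 0, 0.01)
        if (all(f2 > 0)) {
          f2 <- f2 / sum(f2)
          prop <- total_ll(ll_cols, f2)
          acc <- log(runif(1)) < prop - cur
          if (trace) {
            trace_log[[it]] <- list(move = "fraction", sequences = seqs,
                                    fractions = fracs, proposal = f2,
                                    cur_loglik = cur, prop_loglik = prop,
                                    accepted = acc)
          }
          if (acc) {
            fracs <- f2
            cur <- prop
            accepted <- accepted + 1L
          }
        }
      }
      if (it > burn) {
        k <- it - burn
        keep_seq[[k]] <- do.call(rbind, seqs)
        keep_frac[k, ] <- fracs
        keep_ll[k] <- cur
      }
    }
  })

  pvd <- lapply(seq_len(C), function(c) {
    m <- matrix(0, N, N)
    for (k in seq_len(n_keep)) {
      s <- keep_seq[[k]][c, ]
      m[cbind(s, seq_len(N))] <- m[cbind(s, seq_len(N))] + 1
    }
    m / n_keep
  })
  model$mcmc <- list(sequences = keep_seq, fractions = keep_frac,
                     loglik = keep_ll,
                     acceptance_rate = accepted / n_iter,
                     pvd = pvd)
  if (trace) model$mcmc$trace <- trace_log
  model
}

#' Positional variance diagrams of a sampled model
#'
#' @param model a [subtype_model()] carrying MCMC samples.
#' @return List of N x N matrices (one per subtype); entry (e, p) is the
#'   posterior probability that event e occupies position p. Rows sum to 1.
#' @export
positional_variance <- function(model) {
  if (is.null(model$mcmc)) stop("model carries no MCMC samples")
  model$mcmc$pvd
}

#' K-fold cross-validated selection of the number of subtypes
#'
#' Subjects (not scans) are partitioned into K seeded folds; for each fold
#' and each C in 1..C_max, the model is fitted on the training subjects and
#' its mixture log-likelihood evaluated on the held-out subjects.
#' CVIC(C) = sum over folds of -2 x test log-likelihood; the selected C
#' minimizes CVIC.
#'
#' @inheritParams fit_subtypes_path
#' @param K number of folds (default 10).
#' @param subjects per-scan subject identifiers (default: row names of X),
#'   used to keep all scans of a subject in one fold.
#' @return Object of class `cv_result`: `test_loglik` (fold x C matrix),
#'   `cvic` (per C), `selected_C`, `folds` (per-scan fold index).
#' @export
cross_validate <- function(X, grid, sigma = 1, C_max = 2L, K = 10L,
                           settings = fit_settings(), subjects = NULL) {
  X <- as.matrix(X)
  subjects <- subjects %||% rownames(X) %||% as.character(seq_len(nrow(X)))
  uniq <- unique(subjects)
  if (K > length(uniq)) stop("K exceeds the number of subjects")
  fold_of_subj <- with_seed(settings$seed,
                            sample(rep_len(seq_len(K), length(uniq))))
  folds <- fold_of_subj[match(subjects, uniq)]
  test_ll <- matrix(NA_real_, K, C_max,
                    dimnames = list(paste0("fold", seq_len(K)),
                                    paste0("C", seq_len(C_max))))
  for (k in seq_len(K)) {
    tr <- folds != k
    fold_settings <- settings
    fold_settings$seed <- settings$seed + 7919L * k
    path <- fit_subtypes_path(X[tr, , drop = FALSE], grid, sigma,
                              C_max = C_max, settings = fold_settings)
    for (C in seq_len(C_max)) {
      test_ll[k, C] <- mixture_loglik(X[!tr, , drop = FALSE], path[[C]])
    }
  }
  cvic <- colSums(-2 * test_ll)
  structure(list(test_loglik = test_ll, cvic = cvic,
                 selected_C = unname(which.min(cvic)), folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("CVIC by number of subtypes:\n")
  print(x$cvic)
  cat("selected C =", x$selected_C, "\n")
  invisible(x)
}
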