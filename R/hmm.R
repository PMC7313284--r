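# Supervised hidden Markov model over augmented observations.
#
# The hidden state is the activity; the observation at each window is the
# vector of principal-component scores (continuous part, modeled as a
# diagonal-covariance Gaussian per state) optionally concatenated with a
# frame classifier's estimated label (discrete part, modeled as a per-state
# categorical). The two parts are conditionally independent given the state,
# so maximum-likelihood estimation stays closed-form.

#' Bundle continuous and discrete observation streams
#'
#' @param scores T x k numeric matrix of continuous observations (principal
#'   component scores), or `NULL`.
#' @param est_labels Integer vector of discrete observations in 1..N
#'   (estimated activity labels), or `NULL`. At least one part must be given.
#' @param n_classes Number of discrete categories N (required with a
#'   discrete part).
#' @param subjects Optional per-row subject ids; rows of one subject must be
#'   contiguous. Sequences of different subjects are treated as independent.
#' @return An object of class `"obs_seq"`.
#' @export
observation_sequence <- function(scores = NULL, est_labels = NULL,
                                 n_classes = NULL, subjects = NULL) {
  if (is.null(scores) && is.null(est_labels)) {
    stop("at least one of scores / est_labels is required")
  }
  n <- if (!is.null(scores)) {
    scores <- as_feature_matrix(scores, "scores")
    nrow(scores)
  } else {
    length(est_labels)
  }
  if (n < 1L) stop("empty observation sequence")
  if (!is.null(est_labels)) {
    if (is.null(n_classes)) stop("n_classes is required with a discrete part")
    est_labels <- check_labels(est_labels, n_obs = n, n_classes = n_classes)
  }
  if (!is.null(subjects) && length(subjects) != n) {
    stop("subject ids must have one entry per observation")
  }
  structure(
    list(scores = scores, est_labels = est_labels,
         n_classes = if (is.null(n_classes)) NULL else as.integer(n_classes),
         subjects = subjects, n = n),
    class = "obs_seq"
  )
}

as_obs_seq <- function(obs) {
  if (inherits(obs, "obs_seq")) return(obs)
  if (is.matrix(obs) || is.data.frame(obs)) return(observation_sequence(scores = obs))
  stop("obs must be an observation_sequence() or a numeric matrix")
}

#' Fit a supervised HMM from labeled sequences
#'
#' Estimates all parameters in closed form from labeled training data, the
#' labels acting as the (observed) hidden states:
#' * transitions from bigram counts with additive smoothing, bigrams never
#'   crossing a subject boundary;
#' * the initial distribution from overall empirical state frequencies;
#' * per-state Gaussian means and diagonal variances (MLE, variances floored);
#' * per-state categorical over the discrete part with additive smoothing.
#'
#' @param obs An [observation_sequence()] (or a plain score matrix).
#' @param states Integer activity labels 1..N, one per observation; every
#'   state must occur at least once.
#' @param n_states Number of hidden states N; inferred as `max(states)` when
#'   `NULL`.
#' @param smoothing Additive smoothing for transition and categorical
#'   estimates (default 1).
#' @param var_floor Lower bound for emission variances (default 1e-6).
#' @return An object of class `"activity_hmm"`.
#' @export
fit_hmm <- function(obs, states, n_states = NULL, smoothing = 1,
                    var_floor = 1e-6) {
  obs <- as_obs_seq(obs)
  if (is.null(n_states)) n_states <- max(states)
  n_states <- as.integer(n_states)
  states <- check_labels(states, n_obs = obs$n, n_classes = n_states)
  if (smoothing < 0) stop("smoothing must be >= 0")
  occ <- tabulate(states, nbins = n_states)
  if (any(occ == 0L)) {
    stop(sprintf("state %d never occurs in the training labels", which(occ == 0L)[1]))
  }

  runs <- subject_runs(obs$subjects, obs$n)
  trans_counts <- matrix(0, n_states, n_states)
  for (r in runs) {
    if (length(r) < 2L) next
    from <- states[r[-length(r)]]
    to <- states[r[-1L]]
    for (t in seq_along(from)) {
      trans_counts[from[t], to[t]] <- trans_counts[from[t], to[t]] + 1
    }
  }
  A <- (trans_counts + smoothing) /
    (rowSums(trans_counts) + smoothing * n_states)
  if (smoothing == 0 && any(rowSums(trans_counts) == 0)) {
    # a state seen only at sequence ends has no outgoing bigrams; fall back
    # to a uniform row so the matrix stays stochastic
    empty <- rowSums(trans_counts) == 0
    A[empty, ] <- 1 / n_states
  }
  pi0 <- occ / sum(occ)

  means <- NULL; vars <- NULL
  if (!is.null(obs$scores)) {
    k <- ncol(obs$scores)
    means <- matrix(0, n_states, k)
    vars <- matrix(0, n_states, k)
    for (s in seq_len(n_states)) {
      rows <- obs$scores[states == s, , drop = FALSE]
      means[s, ] <- colMeans(rows)
      if (nrow(rows) < 2L) {
        vars[s, ] <- var_floor
        warning(sprintf("state %d has a single observation; variance set to the floor", s))
      } else {
        v <- colMeans(sweep(rows, 2L, means[s, ], "-")^2)  # MLE (divide by n)
        vars[s, ] <- pmax(v, var_floor)
      }
    }
  }

  emit_cat <- NULL
  if (!is.null(obs$est_labels)) {
    n_cat <- obs$n_classes
    emit_cat <- matrix(0, n_states, n_cat)
    for (s in seq_len(n_states)) {
      cnt <- tabulate(obs$est_labels[states == s], nbins = n_cat)
      emit_cat[s, ] <- (cnt + smoothing) / (sum(cnt) + smoothing * n_cat)
    }
  }

  structure(
    list(n_states = n_states, pi = pi0, A = A,
         means = means, vars = vars, emit_cat = emit_cat,
         smoothing = smoothing, var_floor = var_floor,
         trans_counts = trans_counts),
    class = "activity_hmm"
  )
}

#' @export
print.activity_hmm <- function(x, ...) {
  cat(sprintf("Supervised HMM: %d states, %s continuous dims, %s emission\n",
              x$n_states,
              if (is.null(x$means)) "no" else ncol(x$means),
              paste(c(if (!is.null(x$means)) "Gaussian",
                      if (!is.null(x$emit_cat)) "categorical"), collapse = " x ")))
  cat("Transition matrix:\n")
  print(round(x$A, 3))
  invisible(x)
}

# T x N matrix of per-state emission log-densities.
emission_loglik <- function(model, obs) {
  n <- obs$n
  ll <- matrix(0, n, model$n_states)
  if (!is.null(model$means)) {
    if (is.null(obs$scores) || ncol(obs$scores) != ncol(model$means)) {
      stop("observation continuous part does not match the fitted model")
    }
    for (s in seq_len(model$n_states)) {
      d <- sweep(obs$scores, 2L, model$means[s, ], "-")
      ll[, s] <- ll[, s] -
        0.5 * sum(log(2 * pi * model$vars[s, ])) -
        0.5 * drop(d^2 %*% (1 / model$vars[s, ]))
    }
  }
  if (!is.null(model$emit_cat)) {
    if (is.null(obs$est_labels)) stop("model expects a discrete observation part")
    ll <- ll + log(t(model$emit_cat))[obs$est_labels, , drop = FALSE]
  }
  ll
}

#' Log joint probability of an observation/state pair
#'
#' Computes \eqn{\log \pi_{y_1} + \sum_{t \ge 2} \log a_{y_{t-1} y_t} +
#' \sum_t \log b_{y_t}(o_t)}; with several subjects the initial term and the
#' transition chain restart at each subject boundary. Zero-probability
#' transitions return `-Inf` rather than erroring.
#'
#' @param model An `"activity_hmm"`.
#' @param obs An [observation_sequence()] (or score matrix).
#' @param states Integer state sequence, one per observation.
#' @return Log probability (scalar).
#' @export
log_joint <- function(model, obs, states) {
  obs <- as_obs_seq(obs)
  states <- check_labels(states, n_obs = obs$n, n_classes = model$n_states)
  ll <- emission_loglik(model, obs)
  total <- sum(ll[cbind(seq_len(obs$n), states)])
  logA <- log(model$A)
  for (r in subject_runs(obs$subjects, obs$n)) {
    total <- total + log(model$pi[states[r[1L]]])
    if (length(r) > 1L) {
      from <- states[r[-length(r)]]; to <- states[r[-1L]]
      total <- total + sum(logA[cbind(from, to)])
    }
  }
  total
}

#' Most probable state sequence (Viterbi decoding)
#'
#' Log-space dynamic programming over the joint
#' \eqn{p(x, y) = \prod_t p(y_t | y_{t-1}) \, p(x_t | y_t)}; each subject's
#' sequence is decoded independently. Ties are broken toward the smaller
#' state index at every backtracking step.
#'
#' @param model An `"activity_hmm"`.
#' @param obs An [observation_sequence()] (or score matrix).
#' @return Integer vector of decoded states, one per observation.
#' @export
viterbi <- function(model, obs) {
  obs <- as_obs_seq(obs)
  ll <- emission_loglik(model, obs)
  logA <- log(model$A)
  logpi <- log(model$pi)
  out <- integer(obs$n)
  for (r in subject_runs(obs$subjects, obs$n)) {
    Tn <- length(r)
    delta <- logpi + ll[r[1L], ]
    back <- matrix(0L, Tn, model$n_states)
    if (Tn > 1L) {
      for (t in 2:Tn) {
        cand <- delta + logA            # cand[i, j] = delta_i + log a_ij
        best <- apply(cand, 2L, which.max)
        back[t, ] <- best
        delta <- cand[cbind(best, seq_len(model$n_states))] + ll[r[t], ]
      }
    }
    path <- integer(Tn)
    path[Tn] <- which.max(delta)
    if (Tn > 1L) for (t in Tn:2) path[t - 1L] <- back[t, path[t]]
    out[r] <- path
  }
  out
}

#' Exhaustive decoding oracle
#'
#' Enumerates every one of the \eqn{N^T} state sequences and returns the one
#' maximizing [log_joint()], with the same tie rule as [viterbi()] (ties
#' resolved toward the smaller state index at each backtracking position,
#' i.e. preferring smaller \eqn{y_T}, then smaller \eqn{y_{T-1}}, and so on).
#' Intended as a test oracle for small instances.
#'
#' @param model An `"activity_hmm"`.
#' @param obs An [observation_sequence()] (or score matrix) over a single
#'   subject.
#' @return Integer vector of decoded states.
#' @export
brute_force_decode <- function(model, obs) {
  obs <- as_obs_seq(obs)
  N <- model$n_states
  Tn <- obs$n
  if (N^Tn > 1e6) stop("instance too large for exhaustive decoding")
  if (!is.null(obs$subjects) && length(unique(obs$subjects)) > 1L) {
    stop("brute_force_decode handles a single subject sequence")
  }
  ll <- emission_loglik(model, obs)
  logA <- log(model$A)
  logpi <- log(model$pi)
  # expand.grid varies the first factor fastest, so ascending row order
  # prefers smaller y_T, then y_{T-1}, ... — exactly viterbi's tie order.
  seqs <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn), KEEP.OUT.ATTRS = FALSE))
  score <- logpi[seqs[, 1L]] + ll[cbind(1L, seqs[, 1L])]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      score <- score + logA[cbind(seqs[, t - 1L], seqs[, t])] +
        ll[cbind(t, seqs[, t])]
    }
  }
  best <- which.max(score)  # first strict maximum in preference order
  unname(seqs[best, ])
}
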