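# Synthetic activity-sequence generator.
#
# Emulates the structure wearable-sensor activity data exhibits at the
# feature-window level: a sticky first-order Markov chain over activities,
# class-conditional Gaussian feature distributions, and class imbalance
# induced through the chain's stationary distribution (so transition
# structure stays realistic rather than being distorted by subsampling).

#' Transition matrix of the synthetic activity chain
#'
#' Builds \eqn{A = s I + (1 - s) \mathbf{1} w^T} where `s` is the
#' self-transition (stickiness) probability and `w` the normalized imbalance
#' weights; every row sums to 1.
#'
#' @param n_classes Number of activities N.
#' @param stickiness Self-transition probability in \[0, 1).
#' @param weights Positive length-N weights biasing the chain's stationary
#'   distribution (default uniform).
#' @return N x N row-stochastic matrix.
#' @export
build_transition_matrix <- function(n_classes, stickiness = 0.9,
                                    weights = rep(1, n_classes)) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (stickiness < 0 || stickiness >= 1) stop("stickiness must lie in [0, 1)")
  if (length(weights) != n_classes || any(weights <= 0)) {
    stop("weights must be positive and of length n_classes")
  }
  w <- weights / sum(weights)
  stickiness * diag(n_classes) + (1 - stickiness) * matrix(w, n_classes, n_classes, byrow = TRUE)
}

#' Simulate labeled activity sequences
#'
#' Per subject: the initial activity is drawn from the normalized imbalance
#' weights, subsequent activities follow the sticky Markov chain of
#' [build_transition_matrix()], and each window's feature vector is drawn
#' from a spherical Gaussian centered on its activity's mean. Default class
#' means are scaled unit directions `separation * e_i`, making `separation`
#' the single difficulty knob (pairwise mean distance `separation * sqrt(2)`).
#' Output is deterministic given `seed`.
#'
#' @param n_classes Number of activities N (default 6, a typical set of
#'   daily activities).
#' @param n_features Feature dimension p (>= N for the default means).
#' @param len Windows per subject T.
#' @param subjects Number of independent subjects.
#' @param stickiness Self-transition probability (default 0.9; activity
#'   windows of a few seconds make runs tens of windows long).
#' @param separation Distance scale between class means (default 2).
#' @param noise_sd Feature standard deviation around the class mean (default 1).
#' @param weights Imbalance weights (default uniform).
#' @param means Optional N x p matrix of class means overriding the default.
#' @param seed RNG seed.
#' @return List with `x` (T*subjects x p feature matrix), `labels`,
#'   `subjects` (subject id per row), and the generating `transition` matrix.
#' @export
simulate_activity_data <- function(n_classes = 6, n_features = 12, len = 500,
                                   subjects = 1, stickiness = 0.9,
                                   separation = 2, noise_sd = 1,
                                   weights = rep(1, n_classes), means = NULL,
                                   seed = 1) {
  n_classes <- as.integer(n_classes)
  A <- build_transition_matrix(n_classes, stickiness, weights)
  w <- weights / sum(weights)
  if (is.null(means)) {
    if (n_features < n_classes) {
      stop("default means need n_features >= n_classes; supply `means` otherwise")
    }
    means <- matrix(0, n_classes, n_features)
    means[cbind(seq_len(n_classes), seq_len(n_classes))] <- separation
  } else {
    means <- as.matrix(means)
    if (nrow(means) != n_classes || ncol(means) != n_features) {
      stop("means must be an n_classes x n_features matrix")
    }
  }
  total <- len * subjects
  labels <- integer(total)
  subj <- rep(seq_len(subjects), each = len)
  with_seed(seed, {
    for (s in seq_len(subjects)) {
      off <- (s - 1L) * len
      labels[off + 1L] <- sample.int(n_classes, 1L, prob = w)
      if (len > 1L) for (t in 2:len) {
        labels[off + t] <- sample.int(n_classes, 1L, prob = A[labels[off + t - 1L], ])
      }
    }
    x <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(total * n_features, sd = noise_sd), total, n_features)
    list(x = x, labels = labels, subjects = subj, transition = A)
  })
}
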