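# The hybrid WSVM-HMM activity recognizer: the package's central model.
#
# Training pipeline: fit the [-1,1] range scaler -> PCA and component choice
# -> grid-searched weighted SVM on the PCA scores -> out-of-fold SVM label
# estimates -> supervised HMM on scores + estimated labels with the true
# activities as states. Prediction: scale -> project -> SVM labels ->
# Viterbi decoding of the augmented observation stream.

#' Control parameters for the hybrid recognizer
#'
#' @param k Number of principal components to retain; `NULL` chooses the
#'   smallest k reaching `variance_fraction` of total variance.
#' @param variance_fraction Cumulative explained-variance target used when
#'   `k` is `NULL` (default 0.95).
#' @param sigma_grid,c_grid Hyperparameter grids for the cross-validated
#'   search; defaults sigma in {0.1, 0.2, 0.5, 1}, C in {0.1, 1, 5, 10, 100}.
#'   Length-1 grids skip the search.
#' @param folds Stratified cross-validation folds (default 5), used both for
#'   the grid search and for out-of-fold label estimation.
#' @param smoothing Additive smoothing for HMM transition and categorical
#'   estimates (default 1).
#' @param var_floor Emission variance floor (default 1e-6).
#' @param seed Seed for fold assignment; fixes the whole fit.
#' @return A list of class `"hybrid_control"`.
#' @export
hybrid_control <- function(k = NULL, variance_fraction = 0.95,
                           sigma_grid = c(0.1, 0.2, 0.5, 1),
                           c_grid = c(0.1, 1, 5, 10, 100),
                           folds = 5, smoothing = 1, var_floor = 1e-6,
                           seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  if (length(sigma_grid) < 1 || length(c_grid) < 1) stop("grids must be non-empty")
  structure(list(k = k, variance_fraction = variance_fraction,
                 sigma_grid = sigma_grid, c_grid = c_grid, folds = folds,
                 smoothing = smoothing, var_floor = var_floor, seed = seed),
            class = "hybrid_control")
}

#' Concatenate PCA scores with estimated labels into an observation stream
#'
#' The continuous part of the HMM observation is the score matrix; the
#' discrete part is the frame classifier's estimated label. For export the
#' discrete part is one-hot encoded, giving rows of width k + N.
#'
#' @param scores T x k numeric score matrix.
#' @param est_labels Integer labels 1..N, one per row.
#' @param n_classes Number of classes N.
#' @param subjects Optional subject ids.
#' @return An [observation_sequence()] with an `as_matrix` attribute holding
#'   the one-hot exported T x (k + N) matrix.
#' @export
augment_observations <- function(scores, est_labels, n_classes, subjects = NULL) {
  scores <- as_feature_matrix(scores, "scores")
  obs <- observation_sequence(scores, est_labels, n_classes, subjects)
  onehot <- matrix(0, nrow(scores), n_classes)
  onehot[cbind(seq_len(nrow(scores)), obs$est_labels)] <- 1
  attr(obs, "as_matrix") <- cbind(scores, onehot)
  obs
}

#' Fit the hybrid WSVM-HMM activity recognizer
#'
#' Fits the full pipeline on a labeled training stream: range scaling to
#' \[-1, 1\], PCA projection, a stratified-CV grid search for the Gaussian
#' kernel width and base cost, a one-vs-one weighted SVM with per-class
#' costs \eqn{C_i = \mathrm{round}(C \, m_+ / m_i)}, out-of-fold SVM label
#' estimates, and a supervised HMM over the scores augmented with those
#' estimates. Out-of-fold (rather than resubstitution) estimates are used so
#' the HMM's categorical emission reflects the label-error statistics seen
#' at prediction time.
#'
#' @param x Numeric feature matrix, time-ordered windows by rows.
#' @param labels Integer activity labels 1..N, one per row.
#' @param subjects Optional per-row subject ids marking independent
#'   sequences; rows of a subject must be contiguous.
#' @param n_classes Number of classes; inferred as `max(labels)` when `NULL`.
#' @param control A [hybrid_control()] list.
#' @return An object of class `"wsvm_hmm"` with components `normalizer`,
#'   `pca`, `k`, `wsvm`, `hmm`, `control` and a `report` (chosen k, sigma, C,
#'   per-class costs, CV table, out-of-fold accuracy).
#' @examples
#' sim <- simulate_activity_data(n_classes = 3, n_features = 4, len = 120,
#'                               stickiness = 0.9, separation = 2.5, seed = 7)
#' fit <- wsvm_hmm(sim$x, sim$labels,
#'                 control = hybrid_control(sigma_grid = 1, c_grid = 10, seed = 7))
#' mean(predict(fit, sim$x) == sim$labels)
#' @export
wsvm_hmm <- function(x, labels, subjects = NULL, n_classes = NULL,
                     control = hybrid_control()) {
  x <- as_feature_matrix(x)
  if (is.null(n_classes)) n_classes <- max(labels)
  n_classes <- as.integer(n_classes)
  labels <- check_labels(labels, n_obs = nrow(x), n_classes = n_classes)

  norm <- fit_normalizer(x)
  xn <- apply_normalizer(norm, x)
  pca <- fit_pca(xn)
  k <- if (is.null(control$k)) choose_k(pca, control$variance_fraction)
       else as.integer(control$k)
  scores <- pca_transform(pca, xn, k)

  if (length(control$sigma_grid) == 1L && length(control$c_grid) == 1L) {
    search <- list(sigma = control$sigma_grid, C = control$c_grid, table = NULL)
  } else {
    search <- wsvm_grid_search(scores, labels, control$sigma_grid,
                               control$c_grid, folds = control$folds,
                               seed = control$seed)
  }

  scheme <- class_costs(tabulate(labels, nbins = n_classes), search$C)
  svm_fit <- train_wsvm(scores, labels, C = search$C, sigma = search$sigma,
                        scheme = scheme, n_classes = n_classes)
  est <- cv_wsvm_labels(scores, labels, sigma = search$sigma, C = search$C,
                        folds = control$folds, seed = control$seed)
  obs <- augment_observations(scores, est, n_classes, subjects)
  hmm_fit <- fit_hmm(obs, labels, n_states = n_classes,
                     smoothing = control$smoothing,
                     var_floor = control$var_floor)

  structure(
    list(normalizer = norm, pca = pca, k = k, wsvm = svm_fit, hmm = hmm_fit,
         n_classes = n_classes, control = control,
         report = list(k = k, sigma = search$sigma, C = search$C,
                       class_costs = scheme$costs, cv_table = search$table,
                       oof_accuracy = mean(est == labels))),
    class = "wsvm_hmm"
  )
}

#' Predict activities with a fitted hybrid recognizer
#'
#' Applies the training range scaler and PCA projection, labels each window
#' with the weighted SVM, and (for `type = "hybrid"`) smooths the label
#' stream by Viterbi decoding of the HMM over the augmented observations.
#' `type = "wsvm"` returns the framewise SVM labels without smoothing.
#'
#' @param object A `"wsvm_hmm"` fit.
#' @param newdata Numeric feature matrix with the training feature count.
#' @param subjects Optional per-row subject ids; each subject's stream is
#'   decoded independently.
#' @param type `"hybrid"` (default) or `"wsvm"`.
#' @param ... Unused.
#' @return Integer vector of predicted activity labels.
#' @export
predict.wsvm_hmm <- function(object, newdata, subjects = NULL,
                             type = c("hybrid", "wsvm"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata, "newdata")
  xn <- apply_normalizer(object$normalizer, x)
  scores <- pca_transform(object$pca, xn, object$k)
  est <- predict(object$wsvm, scores)
  if (type == "wsvm") return(est)
  obs <- augment_observations(scores, est, object$n_classes, subjects)
  viterbi(object$hmm, obs)
}

#' @export
print.wsvm_hmm <- function(x, ...) {
  cat("Hybrid WSVM-HMM activity recognizer\n")
  cat(sprintf("  classes: %d   retained components: %d\n", x$n_classes, x$k))
  cat(sprintf("  kernel width sigma = %g, base cost C = %g\n",
              x$report$sigma, x$report$C))
  cat("  per-class costs:", paste(x$report$class_costs, collapse = " "), "\n")
  cat(sprintf("  out-of-fold SVM accuracy: %.1f%%\n", 100 * x$report$oof_accuracy))
  invisible(x)
}

#' @export
summary.wsvm_hmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.wsvm_hmm")
}

#' @export
print.summary.wsvm_hmm <- function(x, ...) {
  f <- x$fit
  print(f)
  ev <- f$pca$values / sum(f$pca$values)
  cat(sprintf("  explained variance of retained components: %.1f%%\n",
              100 * sum(ev[seq_len(f$k)])))
  if (!is.null(f$report$cv_table)) {
    cat("  cross-validated accuracy by (sigma, C):\n")
    print(f$report$cv_table)
  }
  cat("  HMM transition matrix:\n")
  print(round(f$hmm$A, 3))
  invisible(x)
}

#' Diagnostic plot of a hybrid fit
#'
#' Left: cumulative explained variance of the principal components with the
#' retained count marked. Right: image of the HMM transition matrix.
#'
#' @param x A `"wsvm_hmm"` fit.
#' @param ... Passed to `plot`.
#' @export
plot.wsvm_hmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cum <- cumsum(x$pca$values) / sum(x$pca$values)
  plot(seq_along(cum), cum, type = "b", xlab = "components",
       ylab = "cumulative explained variance", ylim = c(0, 1), ...)
  graphics::abline(v = x$k, lty = 2)
  graphics::image(seq_len(x$n_classes), seq_len(x$n_classes),
                  t(x$hmm$A)[, x$n_classes:1],
                  xlab = "to state", ylab = "from state", main = "HMM transitions",
                  axes = FALSE)
  graphics::axis(1, at = seq_len(x$n_classes))
  graphics::axis(2, at = seq_len(x$n_classes), labels = x$n_classes:1)
  invisible(x)
}

#' Simulate label sequences from a fitted recognizer's HMM
#'
#' Draws activity label sequences from the fitted initial distribution and
#' transition matrix — useful for inspecting what temporal structure the
#' model has learned.
#'
#' @param object A `"wsvm_hmm"` fit.
#' @param nsim Number of sequences.
#' @param seed RNG seed.
#' @param len Length of each sequence.
#' @param ... Unused.
#' @return A list of integer label sequences.
#' @export
simulate.wsvm_hmm <- function(object, nsim = 1, seed = NULL, len = 100, ...) {
  A <- object$hmm$A
  pi0 <- object$hmm$pi
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      s <- integer(len)
      s[1] <- sample.int(length(pi0), 1L, prob = pi0)
      if (len > 1L) for (t in 2:len) {
        s[t] <- sample.int(length(pi0), 1L, prob = A[s[t - 1L], ])
      }
      s
    })
  })
}
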