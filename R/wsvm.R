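# Class-cost-weighted support vector machine with a Gaussian kernel.
#
# The binary subproblems are solved by an SMO-style dual optimizer with
# per-sample box constraints (the class-dependent costs), maximal-violating-
# pair working-set selection and deterministic tie-breaking, so repeated runs
# are bit-identical. Multiclass classification uses one-vs-one voting.

#' Gaussian (RBF) kernel
#'
#' \eqn{K(x, y) = \exp(-\|x - y\|^2 / 2\sigma^2)}.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return Kernel value in (0, 1].
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# Full Gaussian kernel matrix between rows of a and rows of b.
kernel_matrix <- function(a, b, sigma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Per-class misclassification costs from class counts
#'
#' Scales a base cost by the majority-to-class count ratio,
#' \eqn{C_i = \mathrm{round}(C \cdot m_+ / m_i)}, so that errors on rarer
#' activities are penalized more heavily. Rounding is half away from zero
#' and the result is floored at 1.
#'
#' @param counts Positive integer vector of per-class training counts.
#' @param C Base cost (the cost assigned to the largest class), > 0.
#' @return An object of class `"cost_scheme"`: `base_cost`, `counts`,
#'   `majority` (\eqn{m_+}) and integer `costs` (\eqn{C_i}).
#' @export
class_costs <- function(counts, C) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || any(is.na(counts)) || any(counts < 1L)) {
    stop("class counts must all be >= 1")
  }
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be a positive scalar")
  m_plus <- max(counts)
  costs <- pmax(1, round_half_away(C * m_plus / counts))
  structure(
    list(base_cost = C, counts = counts, majority = m_plus, costs = as.integer(costs)),
    class = "cost_scheme"
  )
}

#' Train a binary weighted SVM
#'
#' Solves the soft-margin dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'       y_i y_j K(x_i, x_j)}
#' subject to \eqn{0 \le \alpha_i \le C_+} for positive samples,
#' \eqn{0 \le \alpha_i \le C_-} for negative samples and
#' \eqn{\sum_i \alpha_i y_i = 0}, with the Gaussian kernel. The two bounds
#' implement class-dependent misclassification penalties. The bias is the
#' mean over free support vectors, or the midpoint of the KKT interval when
#' no support vector is free.
#'
#' @param x Numeric feature matrix.
#' @param y Signed labels, -1/+1, both classes present.
#' @param cost_pos,cost_neg Box bounds for the positive / negative class.
#' @param sigma Gaussian kernel width.
#' @param tol KKT violation tolerance for the stopping rule.
#' @param max_iter Iteration cap; exceeding it raises a convergence error
#'   that reports the remaining KKT gap.
#' @return An object of class `"binary_wsvm"` holding the support vectors,
#'   their signed dual coefficients `alpha * y`, the bias `b` and `sigma`.
#' @export
train_binary_wsvm <- function(x, y, cost_pos, cost_neg, sigma,
                              tol = 1e-3, max_iter = NULL) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("y must have one entry per row of x")
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (!any(y == 1) || !any(y == -1)) stop("both classes must be present")
  if (sigma <= 0) stop("sigma must be positive")
  if (cost_pos <= 0 || cost_neg <= 0) stop("costs must be positive")
  n <- nrow(x)
  if (is.null(max_iter)) max_iter <- max(20000L, 400L * n)

  K <- kernel_matrix(x, x, sigma)
  Q <- (y %o% y) * K
  ub <- ifelse(y > 0, cost_pos, cost_neg)
  alpha <- numeric(n)
  grad <- rep(-1, n)          # gradient of the dual objective, Q %*% alpha - 1
  tau <- 1e-12

  it <- 0L
  repeat {
    it <- it + 1L
    yg <- -y * grad
    up <- (y > 0 & alpha < ub - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < ub - 1e-12)
    if (!any(up) || !any(lo)) break
    gmax <- max(yg[up]); gmin <- min(yg[lo])
    if (gmax - gmin < tol) break
    if (it > max_iter) {
      stop(sprintf("SMO did not converge in %d iterations (KKT gap %.3e)",
                   max_iter, gmax - gmin))
    }
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]

    ai <- alpha[i]; aj <- alpha[j]
    if (y[i] != y[j]) {
      quad <- Q[i, i] + Q[j, j] + 2 * Q[i, j]
      if (quad <= 0) quad <- tau
      delta <- (-grad[i] - grad[j]) / quad
      diffij <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] + delta
      if (diffij > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diffij }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diffij }
      }
      if (diffij > ub[i] - ub[j]) {
        if (alpha[i] > ub[i]) { alpha[i] <- ub[i]; alpha[j] <- ub[i] - diffij }
      } else {
        if (alpha[j] > ub[j]) { alpha[j] <- ub[j]; alpha[i] <- ub[j] + diffij }
      }
    } else {
      quad <- Q[i, i] + Q[j, j] - 2 * Q[i, j]
      if (quad <= 0) quad <- tau
      delta <- (grad[i] - grad[j]) / quad
      sumij <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta
      alpha[j] <- alpha[j] + delta
      if (sumij > ub[i]) {
        if (alpha[i] > ub[i]) { alpha[i] <- ub[i]; alpha[j] <- sumij - ub[i] }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- sumij }
      }
      if (sumij > ub[j]) {
        if (alpha[j] > ub[j]) { alpha[j] <- ub[j]; alpha[i] <- sumij - ub[j] }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- sumij }
      }
    }
    grad <- grad + Q[, i] * (alpha[i] - ai) + Q[, j] * (alpha[j] - aj)
  }

  yg <- -y * grad
  free <- alpha > 1e-8 & alpha < ub - 1e-8
  if (any(free)) {
    b <- mean(yg[free])
  } else {
    up <- (y > 0 & alpha < ub - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < ub - 1e-12)
    hi_v <- if (any(up)) max(yg[up]) else max(yg)
    lo_v <- if (any(lo)) min(yg[lo]) else min(yg)
    b <- (hi_v + lo_v) / 2
  }

  sv <- alpha > 1e-8
  structure(
    list(
      sv = x[sv, , drop = FALSE],
      coef = (alpha * y)[sv],
      alpha = alpha[sv],
      y = y[sv],
      upper = ub[sv],
      b = b,
      sigma = sigma,
      iterations = it,
      sum_alpha_y = sum(alpha * y)
    ),
    class = "binary_wsvm"
  )
}

#' Pre-sign decision values of a binary weighted SVM
#'
#' Returns \eqn{\sum_i \alpha_i y_i K(x, x_i) + b}; the predicted sign is
#' the class.
#'
#' @param model A `"binary_wsvm"`.
#' @param x Numeric matrix (or single vector) of query points.
#' @return Numeric vector of decision values, one per row.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "binary_wsvm"))
  x <- as_feature_matrix(x)
  if (ncol(x) != ncol(model$sv)) {
    stop(sprintf("dimension mismatch: model fitted on %d features, input has %d",
                 ncol(model$sv), ncol(x)))
  }
  drop(kernel_matrix(x, model$sv, model$sigma) %*% model$coef) + model$b
}

#' Train a one-vs-one multiclass weighted SVM
#'
#' Trains one binary weighted SVM per unordered class pair. In the machine
#' for classes (i, j), samples of class i get box bound \eqn{C_i} and samples
#' of class j get \eqn{C_j}, where the per-class costs come from a
#' [class_costs()] scheme (or are recomputed from `labels` and `C`).
#'
#' @param x Numeric feature matrix.
#' @param labels Integer labels 1..N, every class present.
#' @param C Base cost used to build the cost scheme when `scheme` is `NULL`.
#' @param sigma Gaussian kernel width, shared by all machines.
#' @param scheme Optional precomputed `"cost_scheme"` over classes 1..N.
#' @param n_classes Number of classes; inferred from labels when `NULL`.
#' @param weighted If `FALSE`, every class uses the base cost `C` unchanged
#'   (plain unweighted SVM; used for comparisons).
#' @return An object of class `"wsvm"`.
#' @export
train_wsvm <- function(x, labels, C = 1, sigma = 1, scheme = NULL,
                       n_classes = NULL, weighted = TRUE) {
  x <- as_feature_matrix(x)
  if (is.null(n_classes)) n_classes <- max(labels)
  n_classes <- as.integer(n_classes)
  labels <- check_labels(labels, n_obs = nrow(x), n_classes = n_classes)
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0L)) {
    stop(sprintf("class %d has no training samples", which(counts == 0L)[1]))
  }
  if (n_classes < 2L) stop("at least 2 classes are required")
  if (is.null(scheme)) {
    scheme <- if (weighted) class_costs(counts, C)
              else structure(list(base_cost = C, counts = counts,
                                  majority = max(counts),
                                  costs = rep(max(1L, as.integer(round_half_away(C))), n_classes)),
                             class = "cost_scheme")
  }
  if (!weighted) scheme$costs <- rep(C, n_classes)
  pairs <- utils::combn(n_classes, 2L)
  machines <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    ci <- pairs[1L, m]; cj <- pairs[2L, m]
    sel <- labels == ci | labels == cj
    ysub <- ifelse(labels[sel] == ci, 1, -1)   # class i is the +1 side
    machines[[m]] <- train_binary_wsvm(
      x[sel, , drop = FALSE], ysub,
      cost_pos = scheme$costs[ci], cost_neg = scheme$costs[cj],
      sigma = sigma
    )
  }
  structure(
    list(n_classes = n_classes, sigma = sigma, scheme = scheme,
         pairs = pairs, machines = machines, weighted = weighted),
    class = "wsvm"
  )
}

#' Predict activity labels with a one-vs-one weighted SVM
#'
#' Each pairwise machine casts one vote per window; the class with the most
#' votes wins, ties going to the smallest class index.
#'
#' @param object A `"wsvm"` from [train_wsvm()].
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Integer vector of predicted labels 1..N.
#' @export
predict.wsvm <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata, "newdata")
  votes <- matrix(0L, nrow(x), object$n_classes)
  for (m in seq_along(object$machines)) {
    f <- decision_value(object$machines[[m]], x)
    ci <- object$pairs[1L, m]; cj <- object$pairs[2L, m]
    win <- ifelse(f >= 0, ci, cj)
    votes[cbind(seq_len(nrow(x)), win)] <- votes[cbind(seq_len(nrow(x)), win)] + 1L
  }
  apply(votes, 1L, which.max)  # which.max breaks ties toward the smaller index
}

#' @export
print.wsvm <- function(x, ...) {
  cat(sprintf("One-vs-one weighted SVM: %d classes, %d binary machines, sigma = %g\n",
              x$n_classes, length(x$machines), x$sigma))
  cat("Per-class costs:", paste(x$scheme$costs, collapse = " "), "\n")
  invisible(x)
}

#' Grid search of (sigma, C) by stratified cross-validation
#'
#' Evaluates every (sigma, C) pair by stratified k-fold cross-validated
#' accuracy of the weighted one-vs-one SVM (per-class costs recomputed from
#' each fold's training counts) and returns the maximizer. Ties are broken
#' toward the smaller C, then the smaller sigma. Default grids are
#' sigma in {0.1, 0.2, 0.5, 1} and C in {0.1, 1, 5, 10, 100}.
#'
#' @param x Numeric feature matrix.
#' @param labels Integer labels 1..N.
#' @param sigma_grid,c_grid Candidate values.
#' @param folds Number of stratified folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @param weighted Use per-class costs (default) or plain SVM.
#' @return List with `sigma`, `C`, and `table` (a data frame of sigma, C,
#'   cv_accuracy).
#' @export
wsvm_grid_search <- function(x, labels,
                             sigma_grid = c(0.1, 0.2, 0.5, 1),
                             c_grid = c(0.1, 1, 5, 10, 100),
                             folds = 5, seed = 1, weighted = TRUE) {
  x <- as_feature_matrix(x)
  if (length(sigma_grid) < 1L || length(c_grid) < 1L) stop("grids must be non-empty")
  n_classes <- max(labels)
  labels <- check_labels(labels, n_obs = nrow(x))
  fold_id <- stratified_folds(labels, folds, seed)
  grid <- expand.grid(sigma = sigma_grid, C = c_grid, KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      fit <- train_wsvm(x[tr, , drop = FALSE], labels[tr],
                        C = grid$C[g], sigma = grid$sigma[g],
                        n_classes = n_classes, weighted = weighted)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    acc[g] <- correct / length(labels)
  }
  ord <- order(-acc, grid$C, grid$sigma)
  best <- ord[1]
  list(sigma = grid$sigma[best], C = grid$C[best],
       table = data.frame(sigma = grid$sigma, C = grid$C, cv_accuracy = acc))
}

#' Out-of-fold label estimates
#'
#' Gives every training window a predicted label produced by a weighted SVM
#' whose training excluded that window's fold, so the estimates carry the
#' label-error statistics a downstream model will actually see. Per-class
#' costs are recomputed from each fold's training counts.
#'
#' @param x Numeric feature matrix.
#' @param labels Integer labels 1..N.
#' @param sigma,C Kernel width and base cost.
#' @param folds Number of stratified folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @return Integer vector of out-of-fold predicted labels, one per row.
#' @export
cv_wsvm_labels <- function(x, labels, sigma, C, folds = 5, seed = 1) {
  x <- as_feature_matrix(x)
  n_classes <- max(labels)
  labels <- check_labels(labels, n_obs = nrow(x))
  fold_id <- stratified_folds(labels, folds, seed)
  est <- integer(length(labels))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    fit <- train_wsvm(x[tr, , drop = FALSE], labels[tr], C = C, sigma = sigma,
                      n_classes = n_classes)
    est[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  est
}
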