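# Principal component analysis via eigendecomposition of the scatter matrix.

#' Fit principal components to a feature matrix
#'
#' Computes the column mean \eqn{\mu}, the scatter matrix
#' \eqn{S = \sum_j (x_j - \mu)(x_j - \mu)^T} (the unnormalized sum form;
#' its eigenvectors are identical to those of the sample covariance, its
#' eigenvalues are \eqn{(T - 1)} times larger), and the eigendecomposition
#' of \eqn{S}. Eigenpairs are returned sorted by descending eigenvalue and
#' each eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive, which makes results reproducible across runs and platforms.
#'
#' @param x Numeric matrix, T windows x p features, with T >= 2.
#' @return An object of class `"activity_pca"` with fields `mean` (length p),
#'   `vectors` (p x p orthonormal, columns are components), `values`
#'   (eigenvalues of the scatter matrix, descending) and `n_obs`.
#' @export
fit_pca <- function(x) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) stop("PCA requires at least 2 rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  s <- crossprod(xc)                 # scatter matrix, sum form
  eig <- eigen(s, symmetric = TRUE)  # already sorted descending
  v <- eig$vectors
  for (i in seq_len(ncol(v))) {
    j <- which.max(abs(v[, i]))
    if (v[j, i] < 0) v[, i] <- -v[, i]
  }
  structure(
    list(mean = mu, vectors = v, values = pmax(eig$values, 0), n_obs = nrow(x)),
    class = "activity_pca"
  )
}

#' Project data onto the leading principal components
#'
#' @param model An `"activity_pca"` from [fit_pca()].
#' @param x Numeric matrix with the same feature count the model was fitted on.
#' @param k Number of components to retain (defaults to all).
#' @return T x k matrix of principal component scores `(x - mean) %*% V[, 1:k]`.
#' @export
pca_transform <- function(model, x, k = NULL) {
  stopifnot(inherits(model, "activity_pca"))
  x <- as_feature_matrix(x)
  p <- length(model$mean)
  if (ncol(x) != p) {
    stop(sprintf("feature count mismatch: PCA fitted on %d columns, input has %d", p, ncol(x)))
  }
  if (is.null(k)) k <- p
  k <- as.integer(k)
  if (k < 1L || k > p) stop(sprintf("k must be in 1..%d", p))
  sweep(x, 2L, model$mean, "-") %*% model$vectors[, seq_len(k), drop = FALSE]
}

#' Smallest number of components reaching a variance fraction
#'
#' @param model An `"activity_pca"` from [fit_pca()].
#' @param variance_fraction Target cumulative fraction of total variance,
#'   in (0, 1]. With `1.0` the count of strictly positive eigenvalues is
#'   returned.
#' @return Integer number of components.
#' @export
choose_k <- function(model, variance_fraction = 0.95) {
  stopifnot(inherits(model, "activity_pca"))
  if (!is.numeric(variance_fraction) || variance_fraction <= 0 || variance_fraction > 1) {
    stop("variance_fraction must lie in (0, 1]")
  }
  lambda <- model$values
  total <- sum(lambda)
  if (total <= 0) return(1L)
  if (variance_fraction == 1) return(max(1L, sum(lambda > 0)))
  cum <- cumsum(lambda) / total
  as.integer(which(cum >= variance_fraction)[1])
}
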