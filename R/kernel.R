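#' Gaussian kernel matrix
#'
#' Computes `K[i, j] = exp(-||x_i - x_j||^2 / (2 sigma^2))` over the rows of
#' `X`. The bandwidth `sigma` controls the neighborhood size: large values
#' flatten the kernel toward all-ones, small values toward the identity.
#'
#' @param X Numeric samples-by-features matrix.
#' @param sigma Positive bandwidth.
#' @param space_tag Optional label recording which representation the kernel
#'   was built in (stored as an attribute).
#' @return Symmetric samples-by-samples matrix with unit diagonal and
#'   attributes `sigma` and `space_tag`.
#' @export
gaussian_kernel <- function(X, sigma, space_tag = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("sigma must be a positive scalar", call. = FALSE)
  X <- as.matrix(X)
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-d2 / (2 * sigma^2))
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  attr(K, "sigma") <- sigma
  attr(K, "space_tag") <- space_tag
  K
}

#' Ideal target kernel from class labels
#'
#' The label-derived similarity matrix with `+1` where two samples share a
#' label and `-1` otherwise (diagonal `+1`).
#'
#' @param labels Vector of class labels.
#' @return Symmetric matrix of +/-1 entries with attribute
#'   `space_tag = "target"`.
#' @export
target_kernel <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  y <- as.integer(factor(labels))
  same <- outer(y, y, "==")
  K <- matrix(-1, length(y), length(y))
  K[same] <- 1
  attr(K, "space_tag") <- "target"
  K
}

#' Alignment between two kernel matrices
#'
#' Normalized Frobenius inner product
#' `<K1, K2>_F / sqrt(<K1, K1>_F <K2, K2>_F)`, a cosine similarity between
#' kernels: 1 for proportional kernels, scale-invariant in each argument.
#' With a +/-1 target kernel the value can be negative; it is not clamped.
#'
#' @param K1,K2 Same-shape kernel matrices with non-zero Frobenius norm.
#' @return Scalar alignment in `[-1, 1]`.
#' @export
kernel_alignment <- function(K1, K2) {
  if (!all(dim(K1) == dim(K2)))
    stop("kernel matrices must have identical shapes", call. = FALSE)
  n1 <- sum(K1 * K1)
  n2 <- sum(K2 * K2)
  if (n1 == 0 || n2 == 0)
    stop("kernel matrix with zero Frobenius norm", call. = FALSE)
  sum(K1 * K2) / sqrt(n1 * n2)
}

#' Kernel target alignment of a representation
#'
#' Alignment between the Gaussian kernel of `X` and the ideal target kernel
#' of `labels`; measures how well the representation separates the classes
#' at bandwidth `sigma`.
#'
#' @inheritParams gaussian_kernel
#' @param labels Per-row class labels.
#' @return Scalar KTA.
#' @export
kta <- function(X, labels, sigma) {
  if (nrow(as.matrix(X)) != length(labels))
    stop("labels must match the rows of X", call. = FALSE)
  kernel_alignment(gaussian_kernel(X, sigma), target_kernel(labels))
}

#' Default logarithmic bandwidth grid
#'
#' @param from,to Range endpoints.
#' @param length.out Number of grid points.
#' @return Numeric vector, log-spaced.
#' @export
sigma_grid <- function(from = 0.1, to = 100, length.out = 20) {
  exp(seq(log(from), log(to), length.out = length.out))
}

#' Tune the Gaussian bandwidth by maximizing KTA
#'
#' Evaluates [kta()] on every grid point and returns the maximizer along
#' with the full curve, which mirrors the KTA-versus-sigma diagnostics used
#' to compare representations.
#'
#' @inheritParams kta
#' @param grid Numeric vector of candidate bandwidths.
#' @param space_tag Optional label stored in the returned curve.
#' @param subsample Optional number of rows to subsample (the kernel is
#'   O(m^2)); `NULL` uses all rows.
#' @param seed Seed for the subsample draw.
#' @return List with `best_sigma`, `best_kta` and data.frame `curve`
#'   (columns `sigma`, `kta`, `space_tag`).
#' @export
tune_sigma <- function(X, labels, grid = sigma_grid(), space_tag = NA_character_,
                       subsample = NULL, seed = 1L) {
  if (length(grid) == 0L) stop("sigma grid must be non-empty", call. = FALSE)
  X <- as.matrix(X)
  if (!is.null(subsample) && subsample < nrow(X)) {
    set.seed(seed)
    rows <- sort(sample.int(nrow(X), subsample))
    X <- X[rows, , drop = FALSE]
    labels <- labels[rows]
  }
  Kt <- target_kernel(labels)
  d2 <- as.matrix(stats::dist(X))^2
  scores <- vapply(grid, function(s) {
    K <- exp(-d2 / (2 * s^2))
    kernel_alignment(K, Kt)
  }, 0)
  best <- which.max(scores)
  list(best_sigma = grid[best], best_kta = scores[best],
       curve = data.frame(sigma = grid, kta = scores,
                          space_tag = space_tag))
}
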