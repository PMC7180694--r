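#' Kernel specification
#'
#' Describes how a Gram matrix is built from a feature matrix. Linear is
#' the default throughout the package (it is the only kernel the
#' concentration side ever uses, and keeps the sample kernel's rank tied to
#' the sensor count).
#'
#' @param kind one of `"linear"`, `"polynomial"`, `"rbf"`.
#' @param degree polynomial degree (integer >= 1).
#' @param offset polynomial offset (>= 0): `k(x, y) = (x.y + offset)^degree`.
#' @param bandwidth RBF bandwidth `sigma` in
#'   `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`, or `"median"` for the
#'   median heuristic (median over all pairwise Euclidean distances).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf"),
                        degree = 2L, offset = 1, bandwidth = "median") {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    degree <- as.integer(degree)
    if (is.na(degree) || degree < 1L) stop("kernel_spec: degree must be >= 1")
    if (!is.numeric(offset) || offset < 0) {
      stop("kernel_spec: offset must be >= 0")
    }
  }
  if (kind == "rbf") {
    if (!(identical(bandwidth, "median") ||
          (is.numeric(bandwidth) && bandwidth > 0))) {
      stop("kernel_spec: bandwidth must be a positive number or \"median\"")
    }
  }
  structure(list(kind = kind, degree = degree, offset = offset,
                 bandwidth = bandwidth),
            class = "kernel_spec")
}

#' Centering matrix H = I - n^-1 11'
#'
#' The idempotent projector removing the sample mean in feature space;
#' double-centering a Gram matrix as `H K H` is the kernel-space analogue
#' of column-centering the features.
#'
#' @param n sample count, `n >= 2`.
#' @return the dense `n x n` centering matrix.
#' @export
centering_matrix <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("centering_matrix: n must be an integer >= 2")
  diag(n) - 1 / n
}

#' Gram (kernel) matrix of a feature matrix
#'
#' @param features numeric `n x m` matrix, samples as rows, finite values.
#' @param spec a [kernel_spec()].
#' @return symmetric positive semidefinite `n x n` matrix of pairwise
#'   kernel evaluations.
#' @export
gram <- function(features, spec = kernel_spec("linear")) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("gram: features must be finite")
  K <- switch(spec$kind,
    linear = tcrossprod(X),
    polynomial = (tcrossprod(X) + spec$offset)^spec$degree,
    rbf = {
      d <- stats::dist(X)
      bw <- spec$bandwidth
      if (identical(bw, "median")) {
        bw <- stats::median(d)
        if (!is.finite(bw) || bw <= 0) bw <- 1
      }
      D2 <- as.matrix(d)^2
      exp(-D2 / (2 * bw^2))
    }
  )
  (K + t(K)) / 2
}

# Exact double centering H %*% K %*% H without forming H.
double_center <- function(K) {
  rm <- rowMeans(K)
  cm <- colMeans(K)
  gm <- mean(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + gm
}

#' Empirical Hilbert-Schmidt Independence Criterion
#'
#' The biased plug-in HSIC estimate `(n - 1)^-2 tr(K H L H)` between two
#' Gram matrices over the same `n` samples. For positive semidefinite
#' arguments the value is nonnegative, and it is zero iff the doubly
#' centered kernels are orthogonal — for characteristic kernels this is the
#' empirical surrogate of statistical independence. The package minimizes
#' this quantity between projected sensor features and concentration-level
#' features.
#'
#' @param K,L symmetric `n x n` kernel matrices over the same samples,
#'   `n >= 2`.
#' @return a single nonnegative number (up to roundoff).
#' @export
hsic_estimate <- function(K, L) {
  K <- as.matrix(K); L <- as.matrix(L)
  n <- nrow(K)
  if (ncol(K) != n || nrow(L) != n || ncol(L) != n) {
    stop("hsic_estimate: K and L must be square matrices of the same size")
  }
  if (n < 2L) stop("hsic_estimate: need n >= 2")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))) ||
      max(abs(L - t(L))) > 1e-8 * max(1, max(abs(L)))) {
    stop("hsic_estimate: inputs must be symmetric")
  }
  # tr(K H L H) = <K, HLH> elementwise for symmetric inputs
  sum(K * double_center(L)) / (n - 1)^2
}
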