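#' Concentration levels from ppm values
#'
#' A sample at concentration `c` ppm is assigned the raw level
#' `floor(ln c)`; raw levels are then remapped, order-preservingly, to the
#' contiguous indices `1..c_levels`. The logarithmic binning reflects that
#' MOS responses discriminate concentration ratios, not differences.
#'
#' @param concentrations positive numeric vector (ppm).
#' @return integer vector of contiguous level indices, with attributes
#'   `raw_levels` (the `floor(ln c)` values) and `level_map` (named integer
#'   vector raw level -> contiguous index).
#' @export
concentration_levels <- function(concentrations) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) == 0L || anyNA(concentrations) ||
      any(concentrations <= 0)) {
    stop("concentration_levels: concentrations must be positive")
  }
  raw <- as.integer(floor(log(concentrations)))
  u <- sort(unique(raw))
  structure(match(raw, u),
            raw_levels = raw,
            level_map = stats::setNames(seq_along(u), u))
}

#' Concentration-feature matrix Y
#'
#' Builds the `c x n` level-coding matrix: column `j` is the one-hot code
#' of sample `j`'s concentration level if the sample is labeled, and
#' all-zero if it is an unlabeled (target) sample — target concentrations
#' are unknown by the problem statement, and zero columns simply contribute
#' nothing to the concentration kernel.
#'
#' @param levels integer level indices in `1..n_levels`, one per *labeled*
#'   sample, in sample order.
#' @param labeled_mask logical vector of length `n`; `TRUE` where the
#'   sample is labeled. `sum(labeled_mask)` must equal `length(levels)`.
#' @param n total sample count.
#' @param n_levels number of levels `c`; defaults to `max(levels)`.
#' @param level_coded if `TRUE`, code the literal level index instead of 1
#'   (a sensitivity variant of the coding scheme).
#' @return a `c x n` matrix of class `conc_features`.
#' @export
build_concentration_features <- function(levels, labeled_mask, n,
                                         n_levels = NULL,
                                         level_coded = FALSE) {
  labeled_mask <- as.logical(labeled_mask)
  if (length(labeled_mask) != n) {
    stop("build_concentration_features: labeled_mask length != n")
  }
  levels <- as.integer(levels)
  if (length(levels) != sum(labeled_mask)) {
    stop("build_concentration_features: need one level per labeled sample")
  }
  if (is.null(n_levels)) n_levels <- if (length(levels)) max(levels) else 1L
  if (length(levels) && (min(levels) < 1L || max(levels) > n_levels)) {
    stop("build_concentration_features: level index outside 1..", n_levels)
  }
  Y <- matrix(0, nrow = n_levels, ncol = n)
  cols <- which(labeled_mask)
  for (k in seq_along(cols)) {
    Y[levels[k], cols[k]] <- if (level_coded) levels[k] else 1
  }
  structure(Y, class = c("conc_features", "matrix", "array"))
}

#' Linear concentration kernel K_y = Y'Y
#'
#' With one-hot coding, `K_y[i, j] = 1` exactly when samples `i` and `j`
#' are both labeled and share a concentration level, and 0 otherwise;
#' unlabeled samples give zero rows/columns.
#'
#' @param Y a concentration-feature matrix from
#'   [build_concentration_features()].
#' @return symmetric PSD `n x n` matrix.
#' @export
concentration_kernel <- function(Y) {
  crossprod(unclass(Y))
}

# Deterministic eigenvector post-processing: make the largest-|entry|
# component of each column positive, then order columns of (numerically)
# tied eigenvalues lexicographically.
canonicalize_eigenvectors <- function(values, vectors) {
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) vectors[, j] <- -v
  }
  tol <- 1e-10 * max(1, max(abs(values)))
  j <- 1L
  while (j < length(values)) {
    k <- j
    while (k < length(values) && abs(values[k + 1] - values[j]) <= tol) {
      k <- k + 1L
    }
    if (k > j) {
      grp <- j:k
      ord <- do.call(order, as.data.frame(t(vectors[, grp, drop = FALSE])))
      vectors[, grp] <- vectors[, grp[ord], drop = FALSE]
    }
    j <- k + 1L
  }
  vectors
}

#' Fit the concentration-independent kernel subspace (MICF)
#'
#' Finds an orthonormal `W` (`n x h`) maximizing
#' `tr(-W' Kx H Ky H Kx W + mu W' Kx H Kx W)`: projected variance (the
#' kernel-PCA term, weighted by `mu`) minus HSIC-dependence of the
#' projected features on the concentration-level kernel. The maximizer is
#' the set of top-`h` eigenvectors of the symmetric matrix
#' `Kx (-H Ky H + mu H) Kx`, solved densely.
#'
#' When `h = NULL` the dimension is chosen as the number of strictly
#' positive eigenvalues: those are exactly the directions along which the
#' variance reward exceeds the concentration-dependence penalty, so adding
#' any further direction could only lower the objective.
#'
#' @param Kx symmetric `n x n` sample kernel matrix (built over source and
#'   target jointly: the method is transductive and provides no
#'   out-of-sample extension).
#' @param Ky symmetric `n x n` concentration kernel from
#'   [concentration_kernel()].
#' @param mu nonnegative trade-off between variance preservation and
#'   concentration independence; larger values favor variance. Default 1.
#' @param h subspace dimension (`1 <= h <= n`), or `NULL` for the
#'   positive-spectrum rule above.
#' @return an object of class `micf_model`: list with orthonormal `W`
#'   (`n x h`), `mu`, `h`, `eigenvalues` (top `h`, descending), and
#'   `all_eigenvalues`.
#' @export
fit_micf <- function(Kx, Ky, mu = 1, h = NULL) {
  Kx <- as.matrix(Kx); Ky <- as.matrix(Ky)
  n <- nrow(Kx)
  if (ncol(Kx) != n || nrow(Ky) != n || ncol(Ky) != n) {
    stop("fit_micf: Kx and Ky must be square and of the same size")
  }
  if (max(abs(Kx - t(Kx))) > 1e-8 * max(1, max(abs(Kx))) ||
      max(abs(Ky - t(Ky))) > 1e-8 * max(1, max(abs(Ky)))) {
    stop("fit_micf: kernels must be symmetric")
  }
  if (!is.numeric(mu) || mu < 0) stop("fit_micf: mu must be >= 0")
  if (!is.null(h)) {
    h <- as.integer(h)
    if (is.na(h) || h < 1L || h > n) stop("fit_micf: need 1 <= h <= n")
  }
  # A = -H Ky H + mu H, then M = Kx A Kx
  A <- -double_center(Ky) + mu * centering_matrix(n)
  M <- Kx %*% A %*% Kx
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  V <- canonicalize_eigenvectors(e$values, e$vectors)
  if (is.null(h)) {
    pos_tol <- 1e-10 * max(1, max(abs(e$values)))
    h <- max(1L, sum(e$values > pos_tol))
  }
  structure(
    list(W = V[, seq_len(h), drop = FALSE],
         mu = mu, h = h,
         eigenvalues = e$values[seq_len(h)],
         all_eigenvalues = e$values),
    class = "micf_model"
  )
}

#' @export
print.micf_model <- function(x, ...) {
  cat("<micf_model> n =", nrow(x$W), " h =", x$h, " mu =", x$mu, "\n")
  cat("  top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' MICF trace objective
#'
#' Evaluates `tr(-W' Kx H Ky H Kx W + mu W' Kx H Kx W)` for an orthonormal
#' `W`; at the fitted `W` this equals the sum of the retained eigenvalues.
#' Exposed mainly for diagnostics and testing.
#'
#' @param W `n x h` matrix with orthonormal columns.
#' @inheritParams fit_micf
#' @return the objective value (a single number).
#' @export
micf_objective <- function(W, Kx, Ky, mu) {
  W <- as.matrix(W)
  G <- crossprod(W)
  if (max(abs(G - diag(ncol(W)))) > 1e-6) {
    stop("micf_objective: W must have orthonormal columns")
  }
  B <- Kx %*% W
  B <- sweep(B, 2L, colMeans(B), "-")   # B = H Kx W
  -sum(B * (Ky %*% B)) + mu * sum(B * B)
}

#' Project samples into the MICF subspace
#'
#' `Z = W' Kx`: one column per sample (kernel-space column convention;
#' transpose for samples-as-rows use).
#'
#' @param model a fitted [fit_micf()] model.
#' @param Kx `n x n` sample kernel matrix, same samples the model was
#'   fitted on.
#' @return `h x n` matrix of projected features.
#' @export
micf_project <- function(model, Kx) {
  Kx <- as.matrix(Kx)
  if (nrow(Kx) != nrow(model$W)) {
    stop("micf_project: Kx dimension does not match the fitted W")
  }
  t(model$W) %*% Kx
}
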