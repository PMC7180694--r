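#' Fisher scatter matrices
#'
#' Pooled within-class scatter
#' `S_w = sum_i sum_{z in class i} (z - mu_i)(z - mu_i)'` and weighted
#' between-class scatter `S_b = sum_i lambda_i (mu_i - mu)(mu_i - mu)'`,
#' with `lambda_i` defaulting to the class proportion `n_i / n`.
#'
#' @param Z numeric `n x d` matrix, samples as rows.
#' @param labels class label per row (no `NA`); every class must have at
#'   least one sample.
#' @param weights optional named numeric vector of per-class weights
#'   `lambda_i` (names = class labels); default class proportions.
#' @return list with `Sw`, `Sb` (both `d x d`, symmetric PSD),
#'   `class_means`, `overall_mean`, `classes`, `weights`.
#' @export
scatter_matrices <- function(Z, labels, weights = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); d <- ncol(Z)
  if (n < 2L) stop("scatter_matrices: need n >= 2")
  if (length(labels) != n || anyNA(labels)) {
    stop("scatter_matrices: labels must be complete and match rows of Z")
  }
  classes <- sort(unique(labels))
  if (is.null(weights)) {
    tab <- table(factor(labels, levels = classes))
    weights <- stats::setNames(as.numeric(tab) / n, as.character(classes))
  } else {
    if (is.null(names(weights)) ||
        !all(as.character(classes) %in% names(weights))) {
      stop("scatter_matrices: weights must be named by class label")
    }
    weights <- weights[as.character(classes)]
  }
  mu <- colMeans(Z)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  cm <- matrix(NA_real_, length(classes), d,
               dimnames = list(as.character(classes), colnames(Z)))
  for (ci in seq_along(classes)) {
    Zi <- Z[labels == classes[ci], , drop = FALSE]
    mui <- colMeans(Zi)
    cm[ci, ] <- mui
    Di <- sweep(Zi, 2L, mui, "-")
    Sw <- Sw + crossprod(Di)
    dd <- mui - mu
    Sb <- Sb + weights[ci] * tcrossprod(dd)
  }
  list(Sw = (Sw + t(Sw)) / 2, Sb = (Sb + t(Sb)) / 2,
       class_means = cm, overall_mean = mu,
       classes = classes, weights = weights)
}

#' Fisher linear discriminant transform
#'
#' Solves the generalized eigenproblem `S_b V = lambda (S_w + eps I) V`
#' for the `k` leading eigenpairs via the symmetric Cholesky reduction
#' (`S_w + eps I = U'U`, eigen-decompose `U^-T S_b U^-1`), which guarantees
#' real eigenpairs for the PSD pencil. The small ridge `eps` handles
#' singular within-class scatter (few samples, collinear features); by
#' default `eps = 1e-6 tr(S_w)/d`, with an absolute floor when `S_w = 0`.
#'
#' @param Sw,Sb symmetric PSD `d x d` scatter matrices from
#'   [scatter_matrices()].
#' @param k number of discriminant directions, `1 <= k <= d`. At most
#'   `n_classes - 1` directions carry between-class information (the rank
#'   of `S_b`).
#' @param reg ridge `eps` added to `S_w`; `NULL` for the default rule.
#' @return object of class `fld_model`: list with `V` (`d x k`, columns
#'   normalized so that `V'(S_w + eps I)V = I` and sign-canonical),
#'   `gen_eigenvalues` (descending), `regularization`.
#' @export
solve_fld <- function(Sw, Sb, k, reg = NULL) {
  Sw <- as.matrix(Sw); Sb <- as.matrix(Sb)
  d <- nrow(Sw)
  if (ncol(Sw) != d || nrow(Sb) != d || ncol(Sb) != d) {
    stop("solve_fld: Sw and Sb must be square of equal dimension")
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > d) stop("solve_fld: need 1 <= k <= d")
  if (is.null(reg)) {
    reg <- 1e-6 * sum(diag(Sw)) / d
    if (reg <= 0) reg <- 1e-12 * max(1, sum(diag(Sb)) / d)
  }
  U <- chol(Sw + reg * diag(d))
  Ui <- backsolve(U, diag(d))
  C <- t(Ui) %*% Sb %*% Ui
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  V <- Ui %*% canonicalize_eigenvectors(e$values, e$vectors)
  V <- V[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(V = V, gen_eigenvalues = e$values[seq_len(k)],
         all_gen_eigenvalues = e$values, regularization = reg),
    class = "fld_model"
  )
}

#' @export
print.fld_model <- function(x, ...) {
  cat("<fld_model> d =", nrow(x$V), " k =", ncol(x$V),
      " eps =", signif(x$regularization, 3), "\n")
  cat("  generalized eigenvalues:",
      paste(signif(x$gen_eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}
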