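# Benchmark classifier contract: a list with fit(X, y) -> model and
# predict(model, X) -> labels, both deterministic given the stored seed.
# IFLD treats the classifier as a black box through this contract.

new_classifier <- function(fit, predict, name) {
  structure(list(fit = fit, predict = predict, name = name),
            class = "enose_classifier")
}

#' @export
print.enose_classifier <- function(x, ...) {
  cat("<enose_classifier>", x$name, "\n")
  invisible(x)
}

as_feature_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(df)))
  df
}

# Run expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Multinomial logistic regression classifier
#'
#' The package's default benchmark classifier: convex and deterministic,
#' standing in for a shallow neural network with no hidden layer. Wraps
#' [nnet::multinom()].
#'
#' @param decay L2 weight decay passed to the optimizer.
#' @param maxit maximum BFGS iterations.
#' @return an `enose_classifier` (fit/predict pair).
#' @export
classifier_multinom <- function(decay = 0, maxit = 200L) {
  new_classifier(
    fit = function(X, y) {
      df <- as_feature_df(X)
      df$.y <- factor(y)
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            maxit = maxit, decay = decay, MaxNWts = 100000L)
      list(fit = fit, classes = levels(df$.y), integer_y = is.numeric(y))
    },
    predict = function(model, X) {
      p <- as.character(stats::predict(model$fit,
                                       newdata = as_feature_df(X),
                                       type = "class"))
      if (model$integer_y) as.integer(p) else p
    },
    name = "multinom"
  )
}

#' Single-hidden-layer neural network classifier
#'
#' A small feed-forward network (one hidden layer, logistic units) for
#' fidelity with back-propagation classifiers commonly used on E-nose
#' data. Weight initialization is randomized, so fits are seeded; the
#' caller's RNG stream is left untouched.
#'
#' @param size hidden units.
#' @param decay L2 weight decay.
#' @param maxit maximum optimizer iterations.
#' @param seed integer seed for the weight initialization.
#' @return an `enose_classifier`.
#' @export
classifier_mlp <- function(size = 8L, decay = 1e-3, maxit = 300L, seed = 1L) {
  new_classifier(
    fit = function(X, y) {
      df <- as_feature_df(X)
      df$.y <- factor(y)
      fit <- with_seed(seed,
        nnet::nnet(.y ~ ., data = df, size = size, decay = decay,
                   maxit = maxit, trace = FALSE, MaxNWts = 100000L))
      list(fit = fit, classes = levels(df$.y), integer_y = is.numeric(y))
    },
    predict = function(model, X) {
      p <- as.character(stats::predict(model$fit,
                                       newdata = as_feature_df(X),
                                       type = "class"))
      if (model$integer_y) as.integer(p) else p
    },
    name = "mlp"
  )
}

#' Nearest-class-mean classifier
#'
#' Assigns each sample to the class whose training mean is nearest in
#' Euclidean distance (ties broken towards the smaller class label).
#' Exact, parameter-free, and useful as a separability probe.
#'
#' @return an `enose_classifier`.
#' @export
classifier_nearest_mean <- function() {
  new_classifier(
    fit = function(X, y) {
      X <- as.matrix(X)
      classes <- sort(unique(y))
      means <- do.call(rbind, lapply(classes, function(cl) {
        colMeans(X[y == cl, , drop = FALSE])
      }))
      list(means = means, classes = classes)
    },
    predict = function(model, X) {
      X <- as.matrix(X)
      D <- outer(rowSums(X^2), rep(1, nrow(model$means))) -
        2 * X %*% t(model$means) +
        outer(rep(1, nrow(X)), rowSums(model$means^2))
      model$classes[apply(D, 1L, which.min)]
    },
    name = "nearest_mean"
  )
}
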