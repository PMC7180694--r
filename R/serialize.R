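# JSON serialization for fitted transforms: a plain-text container so
# models survive tooling that strips binaries and can be inspected by eye.

#' Write a fitted MICF model to JSON
#'
#' @param model a [fit_micf()] model; an optional `kernel_spec` and
#'   `level_map` stored on it are serialized alongside `W`, `mu`, `h`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_micf_model <- function(model, path) {
  stopifnot(inherits(model, "micf_model"))
  obj <- list(
    type = "micf_model",
    n = nrow(model$W),
    h = model$h,
    mu = model$mu,
    eigenvalues = model$eigenvalues,
    W = unname(as.matrix(model$W)),
    kernel_spec = if (!is.null(model$kernel_spec)) {
      unclass(model$kernel_spec)
    },
    level_map = if (!is.null(model$level_map)) {
      list(raw = as.integer(names(model$level_map)),
           index = as.integer(model$level_map))
    }
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a fitted MICF model from JSON
#'
#' @param path a file written by [write_micf_model()].
#' @return a `micf_model`.
#' @export
read_micf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "micf_model")) {
    stop("read_micf_model: ", path, " is not a serialized MICF model")
  }
  W <- as.matrix(obj$W)
  if (nrow(W) != obj$n || ncol(W) != obj$h) {
    stop("read_micf_model: stored W has inconsistent dimensions")
  }
  m <- list(W = W, mu = obj$mu, h = as.integer(obj$h),
            eigenvalues = as.numeric(obj$eigenvalues))
  if (!is.null(obj$kernel_spec)) {
    ks <- obj$kernel_spec
    m$kernel_spec <- kernel_spec(ks$kind, ks$degree, ks$offset, ks$bandwidth)
  }
  if (!is.null(obj$level_map)) {
    m$level_map <- stats::setNames(as.integer(obj$level_map$index),
                                   obj$level_map$raw)
  }
  structure(m, class = "micf_model")
}
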