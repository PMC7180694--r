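#' Sensor-array sample set
#'
#' The central container of the package: an `n x m` feature matrix (samples
#' as rows, one column per sensor feature) plus per-sample metadata. Labeled
#' ("source") samples carry a class label and an analyte concentration in
#' ppm; unlabeled ("target") samples carry neither. True target labels may
#' be stored in separate *evaluation* fields which no fitting routine in the
#' package ever reads: they exist only so that [accuracy()] can be computed
#' after prediction. This firewall is the contract that makes the protocol
#' transductive.
#'
#' @param features numeric matrix, `n` samples by `m` features; all values
#'   must be finite and `n >= 2`, `m >= 1`.
#' @param labels integer vector of length `n`, with `NA` for unlabeled
#'   (target) samples, or `NULL` for a fully unlabeled set.
#' @param concentrations positive numeric vector of length `n` (ppm), `NA`
#'   exactly where `labels` is `NA`, or `NULL`.
#' @param batch_ids integer vector of length `n`: acquisition batch of each
#'   sample. Batches index time windows; the smallest id is conventionally
#'   the calibration (source) batch.
#' @param roles optional character vector `"source"`/`"target"`; defaults to
#'   `"source"` where a label is present and `"target"` elsewhere.
#' @param eval_labels,eval_concentrations optional hidden ground truth for
#'   target samples (evaluation only). `NA` for source samples is allowed.
#'
#' @return An object of class `sample_set`: a list with elements
#'   `features`, `labels`, `concentrations`, `batch_ids`, `roles`,
#'   `eval_labels`, `eval_concentrations`.
#' @seealso [standardize_per_batch()], [simulate_enose()],
#'   [read_feature_table()], [read_uci_drift_file()]
#' @export
sample_set <- function(features, labels = NULL, concentrations = NULL,
                       batch_ids, roles = NULL,
                       eval_labels = NULL, eval_concentrations = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  m <- ncol(features)
  if (n < 2L) stop("sample_set: need at least 2 samples, got ", n)
  if (m < 1L) stop("sample_set: need at least 1 feature")
  if (!all(is.finite(features))) {
    stop("sample_set: all feature values must be finite")
  }
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("sample_set: labels length != n")
  if (is.null(concentrations)) concentrations <- rep(NA_real_, n)
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != n) {
    stop("sample_set: concentrations length != n")
  }
  has_conc <- !is.na(concentrations)
  if (any(concentrations[has_conc] <= 0)) {
    stop("sample_set: concentrations must be positive (ppm)")
  }
  batch_ids <- as.integer(batch_ids)
  if (length(batch_ids) == 1L) batch_ids <- rep(batch_ids, n)
  if (length(batch_ids) != n || anyNA(batch_ids)) {
    stop("sample_set: batch_ids must be ", n, " finite integers")
  }
  if (is.null(roles)) {
    roles <- ifelse(is.na(labels), "target", "source")
  }
  roles <- as.character(roles)
  if (length(roles) != n || !all(roles %in% c("source", "target"))) {
    stop("sample_set: roles must be 'source' or 'target' for every sample")
  }
  if (any(roles == "source" & is.na(labels))) {
    stop("sample_set: every source sample must carry a label")
  }
  if (any(roles == "target" & !is.na(labels))) {
    stop("sample_set: target samples must not carry a visible label")
  }
  nrm <- function(x, mode) {
    if (is.null(x)) return(rep(if (mode == "i") NA_integer_ else NA_real_, n))
    x <- if (mode == "i") as.integer(x) else as.numeric(x)
    if (length(x) != n) stop("sample_set: evaluation field length != n")
    x
  }
  structure(
    list(
      features = features,
      labels = labels,
      concentrations = concentrations,
      batch_ids = batch_ids,
      roles = roles,
      eval_labels = nrm(eval_labels, "i"),
      eval_concentrations = nrm(eval_concentrations, "d")
    ),
    class = "sample_set"
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$features), " samples x ", ncol(x$features),
      " features\n", sep = "")
  cat("  batches: ", paste(sort(unique(x$batch_ids)), collapse = ", "), "\n",
      sep = "")
  cat("  source: ", sum(x$roles == "source"),
      "   target: ", sum(x$roles == "target"), "\n", sep = "")
  invisible(x)
}

n_samples <- function(s) nrow(s$features)
n_features <- function(s) ncol(s$features)

# Row subset preserving all per-sample fields and sample order.
subset_samples <- function(s, idx) {
  sample_set(
    features = s$features[idx, , drop = FALSE],
    labels = s$labels[idx],
    concentrations = s$concentrations[idx],
    batch_ids = s$batch_ids[idx],
    roles = s$roles[idx],
    eval_labels = s$eval_labels[idx],
    eval_concentrations = s$eval_concentrations[idx]
  )
}

#' Hide the labels of selected batches for transductive evaluation
#'
#' Moves the visible labels and concentrations of every sample in `batches`
#' into the hidden evaluation fields and marks those samples as targets.
#' This is how a fully labeled archive (e.g. read from disk) is turned into
#' the source/target split of the batch protocol without destroying the
#' ground truth needed for scoring.
#'
#' @param s a [sample_set()].
#' @param batches integer batch ids to conceal.
#' @return a `sample_set` with the selected batches unlabeled.
#' @export
conceal_batches <- function(s, batches) {
  hide <- s$batch_ids %in% batches
  ev_l <- s$eval_labels
  ev_c <- s$eval_concentrations
  ev_l[hide] <- s$labels[hide]
  ev_c[hide] <- s$concentrations[hide]
  lab <- s$labels
  conc <- s$concentrations
  lab[hide] <- NA_integer_
  conc[hide] <- NA_real_
  roles <- s$roles
  roles[hide] <- "target"
  sample_set(s$features, lab, conc, s$batch_ids, roles, ev_l, ev_c)
}

# True label per sample (visible for source, hidden for target); used only
# by writers that export fully labeled archives and by scoring.
true_labels <- function(s) {
  ifelse(is.na(s$labels), s$eval_labels, s$labels)
}

true_concentrations <- function(s) {
  ifelse(is.na(s$concentrations), s$eval_concentrations, s$concentrations)
}
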