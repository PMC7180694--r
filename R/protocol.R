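#' Classification accuracy
#'
#' @param y_true,y_pred equal-length label vectors (length >= 1).
#' @return fraction of agreeing positions in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("accuracy: length mismatch (", length(y_true), " vs ",
         length(y_pred), ")")
  }
  if (length(y_true) == 0L) stop("accuracy: empty label vectors")
  mean(y_true == y_pred)
}

#' Train-on-first-batch drift-compensation protocol
#'
#' The standard evaluation protocol for drift compensation: the batch with
#' the smallest id is the fully labeled source (calibration) domain; every
#' later batch is an unlabeled target domain, adapted and scored
#' separately against the source (or pooled with `pool_targets = TRUE`).
#' Per target batch the pipeline is: per-batch standardization, sample
#' kernel `Kx` over the source+target union, concentration kernel `Ky`
#' from source concentrations only, [fit_micf()], projection, and either a
#' direct classifier fit on the projected source (`method = "micf"`) or
#' pseudo-label refinement with [run_ifld()] (`method = "micf_ifld"`).
#' `method = "baseline"` skips the subspace entirely and fits the same
#' classifier on standardized raw features. Hidden target labels are read
#' only when scoring the returned predictions, never during fitting.
#'
#' Projected features are re-standardized (zero mean, unit variance over
#' the union) before classification; this affine step only conditions the
#' optimizer and does not change the subspace.
#'
#' @param data a [sample_set()] with at least two batches; the smallest
#'   batch must be fully labeled and targets must carry hidden evaluation
#'   labels for scoring.
#' @param method `"micf_ifld"` (default), `"micf"`, or `"baseline"`.
#' @param kernel [kernel_spec()] for the sample kernel `Kx`.
#' @param mu MICF trade-off, passed to [fit_micf()].
#' @param h MICF subspace dimension (`NULL` = positive-spectrum rule).
#' @param classifier an `enose_classifier`.
#' @param k,max_iter,tol IFLD parameters, see [run_ifld()].
#' @param level_coded concentration coding variant, see
#'   [build_concentration_features()].
#' @param pool_targets adapt all target batches jointly instead of one
#'   batch at a time (accuracy is still reported per batch).
#' @param seed run-level seed recorded in the result and applied before
#'   each adaptation (relevant only for stochastic classifiers).
#' @return object of class `protocol_result`: list with `per_batch`
#'   (data.frame: batch, n, n_correct, accuracy), `average_accuracy`
#'   (unweighted mean over target batches), `method_tag`, `predictions`
#'   (per-batch list), `run_config`, `seed`.
#' @export
run_batch_protocol <- function(data,
                               method = c("micf_ifld", "micf", "baseline"),
                               kernel = kernel_spec("linear"),
                               mu = 1, h = NULL,
                               classifier = classifier_multinom(),
                               k = NULL, max_iter = 20L, tol = 0,
                               level_coded = FALSE,
                               pool_targets = FALSE,
                               seed = 1L) {
  method <- match.arg(method)
  batches <- sort(unique(data$batch_ids))
  if (length(batches) < 2L) {
    stop("run_batch_protocol: need at least 2 batches, got ",
         length(batches))
  }
  src_b <- batches[1]
  src_idx <- which(data$batch_ids == src_b)
  if (anyNA(data$labels[src_idx])) {
    stop("run_batch_protocol: source batch ", src_b, " must be fully labeled")
  }
  data <- standardize_per_batch(data)
  src <- subset_samples(data, src_idx)
  target_batches <- batches[-1]
  groups <- if (pool_targets) list(target_batches) else as.list(target_batches)

  per_rows <- list()
  predictions <- list()
  for (grp in groups) {
    tgt_idx <- which(data$batch_ids %in% grp)
    tgt <- subset_samples(data, tgt_idx)
    set.seed(seed)
    pred <- adapt_and_predict(src, tgt, method, kernel, mu, h,
                              classifier, k, max_iter, tol, level_coded)
    # scoring: the only place hidden labels are read
    for (b in grp) {
      bi <- tgt$batch_ids == b
      yt <- tgt$eval_labels[bi]
      if (anyNA(yt)) {
        stop("run_batch_protocol: target batch ", b,
             " lacks hidden evaluation labels; cannot score")
      }
      acc <- accuracy(yt, pred[bi])
      per_rows[[as.character(b)]] <- data.frame(
        batch = b, n = sum(bi), n_correct = sum(yt == pred[bi]),
        accuracy = acc)
      predictions[[as.character(b)]] <- pred[bi]
    }
  }
  per_batch <- do.call(rbind, per_rows[as.character(target_batches)])
  rownames(per_batch) <- NULL
  structure(
    list(per_batch = per_batch,
         average_accuracy = mean(per_batch$accuracy),
         method_tag = method,
         predictions = predictions,
         run_config = list(method = method, kernel = kernel, mu = mu, h = h,
                           classifier = classifier$name, k = k,
                           max_iter = max_iter, tol = tol,
                           level_coded = level_coded,
                           pool_targets = pool_targets, seed = seed),
         seed = seed),
    class = "protocol_result"
  )
}

# One source/target adaptation. Sees only visible fields of src/tgt.
adapt_and_predict <- function(src, tgt, method, kernel, mu, h,
                              classifier, k, max_iter, tol, level_coded) {
  if (method == "baseline") {
    m <- classifier$fit(src$features, src$labels)
    return(classifier$predict(m, tgt$features))
  }
  n_s <- n_samples(src)
  n <- n_s + n_samples(tgt)
  X <- rbind(src$features, tgt$features)
  Kx <- gram(X, kernel)
  lev <- concentration_levels(src$concentrations)
  Y <- build_concentration_features(lev, c(rep(TRUE, n_s),
                                           rep(FALSE, n - n_s)),
                                    n, level_coded = level_coded)
  Ky <- concentration_kernel(Y)
  model <- fit_micf(Kx, Ky, mu = mu, h = h)
  Z <- t(micf_project(model, Kx))            # samples as rows
  mu_z <- colMeans(Z)
  sd_z <- sqrt(colMeans(sweep(Z, 2L, mu_z)^2))
  Z <- sweep(sweep(Z, 2L, mu_z), 2L, sd_z + 1e-12, "/")
  Zs <- Z[seq_len(n_s), , drop = FALSE]
  Zt <- Z[-seq_len(n_s), , drop = FALSE]
  if (method == "micf") {
    m <- classifier$fit(Zs, src$labels)
    classifier$predict(m, Zt)
  } else {
    res <- run_ifld(Zs, src$labels, Zt, clf = classifier, k = k,
                    max_iter = max_iter, tol = tol)
    res$pseudo_labels
  }
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> method:", x$method_tag, "\n")
  tab <- x$per_batch
  tab$accuracy <- sprintf("%.4f", tab$accuracy)
  print(tab, row.names = FALSE)
  cat(sprintf("average\t%.4f\n", x$average_accuracy))
  invisible(x)
}

#' Run the batch protocol on a directory of archive-dialect files
#'
#' Convenience wrapper: reads every `batch<k>.dat` file in `dir` with
#' [read_uci_drift_file()], conceals all batches except the smallest into
#' hidden evaluation fields, and calls [run_batch_protocol()].
#'
#' @param dir directory containing `batch1.dat`, `batch2.dat`, ...
#' @param pattern filename regular expression, default
#'   `"^batch[0-9]+\\.dat$"`.
#' @param n_features fixed feature count passed to the reader (`NULL` to
#'   infer per file).
#' @param ... passed on to [run_batch_protocol()].
#' @return a `protocol_result`.
#' @export
run_uci_protocol <- function(dir, pattern = "^batch[0-9]+\\.dat$",
                             n_features = NULL, ...) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) < 2L) {
    stop("run_uci_protocol: need at least 2 batch files in ", dir)
  }
  sets <- lapply(files, read_uci_drift_file, n_features = n_features)
  m <- max(vapply(sets, function(s) ncol(s$features), 0L))
  pad <- function(s) {
    if (ncol(s$features) == m) return(s)
    X <- cbind(s$features,
               matrix(0, nrow(s$features), m - ncol(s$features)))
    sample_set(X, s$labels, s$concentrations, s$batch_ids, s$roles,
               s$eval_labels, s$eval_concentrations)
  }
  sets <- lapply(sets, pad)
  all <- do.call(rbind_samples, sets)
  all <- conceal_batches(all, setdiff(unique(all$batch_ids),
                                      min(all$batch_ids)))
  run_batch_protocol(all, ...)
}

# Concatenate sample sets sharing a feature dimension.
rbind_samples <- function(...) {
  ss <- list(...)
  sample_set(
    features = do.call(rbind, lapply(ss, `[[`, "features")),
    labels = unlist(lapply(ss, `[[`, "labels")),
    concentrations = unlist(lapply(ss, `[[`, "concentrations")),
    batch_ids = unlist(lapply(ss, `[[`, "batch_ids")),
    roles = unlist(lapply(ss, `[[`, "roles")),
    eval_labels = unlist(lapply(ss, `[[`, "eval_labels")),
    eval_concentrations = unlist(lapply(ss, `[[`, "eval_concentrations"))
  )
}
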