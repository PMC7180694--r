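#' Read one batch file in the gas-sensor-drift archive dialect
#'
#' Parses the libsvm-like dialect used by the public multi-year gas sensor
#' drift archives: one sample per line,
#' `label;concentration i1:v1 i2:v2 ...` with a positive integer class
#' label, a positive concentration in ppm, and strictly increasing integer
#' feature indices. Feature indices absent from a line are filled with 0.
#'
#' @param path path to a batch file. Unless `batch_id` is given, the batch
#'   number is parsed from a `batch<k>` stem in the file name.
#' @param batch_id optional integer overriding the filename-derived batch.
#' @param n_features optional fixed feature count (e.g. 128 for the 16-
#'   sensor, 8-features-per-sensor archive); by default the largest index
#'   seen in the file. Indices above `n_features` are a format error.
#' @return a [sample_set()] in which every sample is labeled (role
#'   `"source"`); use [conceal_batches()] to build a transductive split.
#' @export
read_uci_drift_file <- function(path, batch_id = NULL, n_features = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("read_uci_drift_file: no samples in ", path)
  if (is.null(batch_id)) {
    m <- regmatches(basename(path),
                    regexec("batch([0-9]+)", basename(path)))[[1]]
    if (length(m) < 2L) {
      stop("read_uci_drift_file: cannot parse batch id from file name '",
           basename(path), "'; pass batch_id explicitly")
    }
    batch_id <- as.integer(m[2])
  }
  parsed <- vector("list", length(keep))
  labels <- integer(length(keep))
  concs <- numeric(length(keep))
  for (r in seq_along(keep)) {
    ln <- keep[r]
    toks <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    hd <- regmatches(toks[1], regexec("^([0-9]+);([0-9.eE+-]+)$", toks[1]))[[1]]
    if (length(hd) != 3L) {
      stop("read_uci_drift_file: malformed 'label;concentration' field at line ",
           ln)
    }
    g <- as.integer(hd[2])
    cc <- as.numeric(hd[3])
    if (is.na(g) || g < 1L || is.na(cc) || cc <= 0) {
      stop("read_uci_drift_file: invalid label or concentration at line ", ln)
    }
    feats <- toks[-1]
    if (length(feats) == 0L) {
      stop("read_uci_drift_file: no features at line ", ln)
    }
    sp <- strsplit(feats, ":", fixed = TRUE)
    if (any(lengths(sp) != 2L)) {
      stop("read_uci_drift_file: malformed 'index:value' pair at line ", ln)
    }
    idx <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
    val <- suppressWarnings(as.numeric(vapply(sp, `[`, "", 2L)))
    if (anyNA(idx) || anyNA(val)) {
      stop("read_uci_drift_file: non-numeric 'index:value' pair at line ", ln)
    }
    if (any(idx < 1L)) {
      stop("read_uci_drift_file: feature index out of range at line ", ln)
    }
    if (any(diff(idx) <= 0L)) {
      stop("read_uci_drift_file: duplicate or non-increasing feature index at line ",
           ln)
    }
    labels[r] <- g
    concs[r] <- cc
    parsed[[r]] <- list(idx = idx, val = val)
  }
  m_max <- max(vapply(parsed, function(p) max(p$idx), 0L))
  if (is.null(n_features)) {
    n_features <- m_max
  } else if (m_max > n_features) {
    stop("read_uci_drift_file: feature index ", m_max,
         " exceeds n_features = ", n_features)
  }
  X <- matrix(0, nrow = length(keep), ncol = n_features)
  for (r in seq_along(parsed)) {
    X[r, parsed[[r]]$idx] <- parsed[[r]]$val
  }
  sample_set(X, labels = labels, concentrations = concs,
             batch_ids = batch_id)
}

#' Write a sample set in the gas-sensor-drift archive dialect
#'
#' Emits one fully labeled line per sample (the archive dialect has no
#' notion of an unlabeled sample, mirroring the public archives whose
#' labels are hidden only at protocol time). Hidden evaluation labels and
#' concentrations are used for target samples, so writing requires ground
#' truth for every sample.
#'
#' @param s a [sample_set()] with a true label and concentration for every
#'   sample (visible or in the evaluation fields).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_uci_drift_file <- function(s, path) {
  lab <- true_labels(s)
  conc <- true_concentrations(s)
  if (anyNA(lab) || anyNA(conc)) {
    stop("write_uci_drift_file: every sample needs a true label and concentration")
  }
  X <- s$features
  lines <- vapply(seq_len(nrow(X)), function(r) {
    paste0(sprintf("%d;%.9f", lab[r], conc[r]), " ",
           paste(sprintf("%d:%.17g", seq_len(ncol(X)), X[r, ]),
                 collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a delimited feature table into a sample set
#'
#' Generic reader for header-ed delimited text. Column roles are given by a
#' schema; rows with an empty/missing label cell become unlabeled target
#' samples. Feature columns may be named explicitly (any column order then
#' yields the same sample set) or left `NULL` to take every unassigned
#' column in file order.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema list with entries `label`, `concentration`, `batch`
#'   (column names; `label`/`concentration` may be `NULL` if absent),
#'   optional `features` (character vector), and optional `eval_label`,
#'   `eval_concentration` for hidden ground-truth columns.
#' @param sep field separator, default `","`.
#' @return a [sample_set()].
#' @export
read_feature_table <- function(path,
                               schema = list(label = "label",
                                             concentration = "concentration",
                                             batch = "batch"),
                               sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_feature_table: no samples in ", path)
  need <- function(col, what) {
    if (!is.null(col) && !col %in% names(df)) {
      stop("read_feature_table: schema names ", what, " column '", col,
           "' absent from header")
    }
    col
  }
  bcol <- need(schema$batch, "batch")
  if (is.null(bcol)) stop("read_feature_table: schema must name a batch column")
  lcol <- need(schema$label, "label")
  ccol <- need(schema$concentration, "concentration")
  elcol <- need(schema$eval_label, "eval_label")
  eccol <- need(schema$eval_concentration, "eval_concentration")
  reserved <- c(bcol, lcol, ccol, elcol, eccol, "role")
  fcols <- schema$features
  if (is.null(fcols)) {
    fcols <- setdiff(names(df), reserved)
  } else {
    miss <- setdiff(fcols, names(df))
    if (length(miss)) {
      stop("read_feature_table: feature column(s) absent: ",
           paste(miss, collapse = ", "))
    }
  }
  if (length(fcols) == 0L) stop("read_feature_table: no feature columns")
  for (fc in fcols) {
    v <- df[[fc]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !all(is.na(v) == is.na(v2))) {
        stop("read_feature_table: non-numeric value in feature column '",
             fc, "'")
      }
      df[[fc]] <- v2
    }
  }
  X <- as.matrix(df[fcols])
  colnames(X) <- fcols
  sample_set(
    features = X,
    labels = if (is.null(lcol)) NULL else df[[lcol]],
    concentrations = if (is.null(ccol)) NULL else df[[ccol]],
    batch_ids = df[[bcol]],
    eval_labels = if (is.null(elcol)) NULL else df[[elcol]],
    eval_concentrations = if (is.null(eccol)) NULL else df[[eccol]]
  )
}

#' Write a sample set as a delimited feature table
#'
#' Deterministic column order: `batch`, `label`, `concentration`, then the
#' feature columns `f1..fm` (or the stored column names). Hidden evaluation
#' fields are written only on request, under `eval_label` /
#' `eval_concentration`, so a default export never leaks target ground
#' truth.
#'
#' @param s a [sample_set()].
#' @param path output file path.
#' @param include_eval write the hidden evaluation columns as well.
#' @param sep field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(s, path, include_eval = FALSE, sep = ",") {
  X <- s$features
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(batch = s$batch_ids, label = s$labels,
                   concentration = s$concentrations,
                   check.names = FALSE)
  if (include_eval) {
    df$eval_label <- s$eval_labels
    df$eval_concentration <- s$eval_concentrations
  }
  Xd <- as.data.frame(X)
  names(Xd) <- fn
  df <- cbind(df, Xd)
  utils::write.table(df, path, sep = sep, row.names = FALSE, col.names = TRUE,
                     qmethod = "double", quote = FALSE)
  invisible(path)
}

#' Per-batch feature standardization
#'
#' Within every acquisition batch, each feature is shifted to zero mean and
#' scaled to unit variance (population convention, `1/n`). A guard of
#' `1e-12` is added to the standard deviation, so a feature that is
#' constant within a batch maps to exactly 0 rather than dividing by zero.
#' This is the preprocessing applied before any kernel is built: it removes
#' batch-wide gain and offset, leaving the within-batch structure that the
#' subspace methods operate on. The operation is idempotent up to the
#' guard.
#'
#' @param s a [sample_set()]; every batch must contain at least one sample.
#' @return a `sample_set` with standardized features; order, labels, and
#'   batch structure untouched.
#' @export
standardize_per_batch <- function(s) {
  X <- s$features
  for (b in unique(s$batch_ids)) {
    i <- which(s$batch_ids == b)
    Xi <- X[i, , drop = FALSE]
    mu <- colMeans(Xi)
    Xi <- sweep(Xi, 2L, mu, "-")
    sd_pop <- sqrt(colMeans(Xi^2))
    X[i, ] <- sweep(Xi, 2L, sd_pop + 1e-12, "/")
  }
  out <- s
  out$features <- X
  out
}
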