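#' Per-trial feature table
#'
#' Rows are trials, columns are named features. Names encode provenance:
#' `"ar:C3:a2"` is the lag-2 Burg coefficient of channel C3;
#' `"dtf30:FC1->Cz"` is the DTF flow FC1 to Cz at 30 Hz.
#'
#' @param X numeric matrix, trials x features, finite.
#' @param feature_names unique character vector, length `ncol(X)`.
#' @param class_labels per-trial labels in `{-1, +1}`, length `nrow(X)`.
#' @param provenance list describing how the features were made; must
#'   contain `$kind` in `{"ar", "dtf", "fused", "external"}`.
#' @return an object of class `"feature_table"`.
#' @export
feature_table <- function(X, feature_names, class_labels,
                          provenance = list(kind = "external")) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) > 0 && !all(is.finite(X)))
    stop("feature matrix contains non-finite entries", call. = FALSE)
  if (length(feature_names) != ncol(X))
    stop("feature_names length must equal ncol(X)", call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("feature names must be unique", call. = FALSE)
  if (length(class_labels) != nrow(X))
    stop("class_labels length must equal nrow(X)", call. = FALSE)
  if (!all(class_labels %in% c(-1L, 1L)))
    stop("class_labels must all be -1 or +1", call. = FALSE)
  colnames(X) <- feature_names
  structure(list(X = X, feature_names = as.character(feature_names),
                 class_labels = as.integer(class_labels),
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d features (%s)\n",
              nrow(x$X), ncol(x$X), x$provenance$kind))
  invisible(x)
}

#' Univariate AR-parameter features
#'
#' Per trial and channel, fits a Burg AR(p) model and concatenates the
#' coefficients channel-major, giving `N * p` features per trial
#' (`C3:a1..a_p`, then `C4:a1..a_p`, ...). These are the classic
#' single-channel motor-imagery features; they carry each channel's
#' spectral shape but no cross-channel information.
#'
#' @param ts a [trialset()].
#' @param order AR order `p` (default 6), fixed across trials so feature
#'   vectors have a common length.
#' @return a [feature_table()] with provenance kind `"ar"`.
#' @export
ar_features <- function(ts, order = 6L) {
  validate_trialset(ts)
  N <- n_channels(ts); p <- as.integer(order)
  X <- matrix(NA_real_, n_trials(ts), N * p)
  for (i in seq_len(n_trials(ts)))
    for (j in seq_len(N)) {
      fit <- tryCatch(fit_ar_burg(ts$data[i, j, ], p), error = function(e)
        stop(sprintf("AR fit failed on trial %d, channel %s: %s",
                     i, ts$channel_labels[j], conditionMessage(e)), call. = FALSE))
      X[i, ((j - 1) * p + 1):(j * p)] <- fit$coeffs
    }
  nm <- as.vector(vapply(ts$channel_labels, function(ch)
    paste0("ar:", ch, ":a", seq_len(p)), character(p)))
  feature_table(X, nm, ts$class_labels,
                provenance = list(kind = "ar", order = p,
                                  channels = ts$channel_labels))
}

# format a frequency for a feature name: 30 -> "30", 12.5 -> "12.5"
.fmt_freq <- function(f) format(f, trim = TRUE, scientific = FALSE)

#' DTF network-flow features
#'
#' Per trial, fits one MVAR model over all channels, evaluates the DTF at
#' the requested frequencies, and vectorises the directed-pair entries:
#' `|freqs| * N * (N - 1)` features per trial when the diagonal (self-flow)
#' is excluded, `|freqs| * N^2` when included. Feature
#' `"dtf30:C3->C4"` is `gamma2[C4, C3]` at 30 Hz.
#'
#' The MVAR order is either a fixed integer or `"aic"`, in which case a
#' single order is selected on a calibration subset (the first
#' `min(10, trials)` trials) and then held fixed for every trial, so all
#' trials share one feature dimensionality.
#'
#' @param ts a [trialset()].
#' @param freqs frequencies in Hz (default `c(10, 15, 20, 25, 30)`).
#' @param mvar_order integer order, or `"aic"`.
#' @param include_diagonal keep self-flow features `ch->ch`? default `FALSE`.
#' @param method MVAR estimator, see [fit_mvar()].
#' @param aic_p_max largest candidate order when `mvar_order = "aic"`
#'   (default 10).
#' @return a [feature_table()] with provenance kind `"dtf"`.
#' @export
dtf_features <- function(ts, freqs = c(10, 15, 20, 25, 30), mvar_order = "aic",
                         include_diagonal = FALSE, method = c("ls", "burg"),
                         aic_p_max = 10L) {
  validate_trialset(ts)
  method <- match.arg(method)
  if (any(freqs >= ts$fs / 2))
    stop("every frequency must be below the Nyquist rate fs/2", call. = FALSE)
  N <- n_channels(ts)
  if (identical(mvar_order, "aic")) {
    calib <- trialset(ts$data[seq_len(min(10L, n_trials(ts))), , , drop = FALSE],
                      ts$fs, ts$channel_labels,
                      ts$class_labels[seq_len(min(10L, n_trials(ts)))],
                      ts$epoch_window)
    mvar_order <- select_order_aic(calib, p_max = aic_p_max, method = method)$order
  }
  p <- as.integer(mvar_order)

  labs <- ts$channel_labels
  pair_idx <- expand.grid(to = seq_len(N), from = seq_len(N))
  if (!include_diagonal) pair_idx <- pair_idx[pair_idx$to != pair_idx$from, ]
  pair_idx <- pair_idx[order(pair_idx$from, pair_idx$to), ]

  nm <- as.vector(vapply(freqs, function(f)
    paste0("dtf", .fmt_freq(f), ":",
           labs[pair_idx$from], "->", labs[pair_idx$to]),
    character(nrow(pair_idx))))
  X <- matrix(NA_real_, n_trials(ts), length(freqs) * nrow(pair_idx))
  for (i in seq_len(n_trials(ts))) {
    trial <- ts$data[i, , , drop = TRUE]
    model <- tryCatch(
      fit_mvar(trial, order = p, method = method, fs = ts$fs,
               channel_labels = labs),
      error = function(e)
        stop(sprintf("MVAR fit failed on trial %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    d <- dtf_matrix(model, freqs)
    X[i, ] <- as.vector(vapply(d$gamma2, function(g)
      g[cbind(pair_idx$to, pair_idx$from)], numeric(nrow(pair_idx))))
  }
  feature_table(X, nm, ts$class_labels,
                provenance = list(kind = "dtf", order = p, freqs = freqs,
                                  include_diagonal = include_diagonal,
                                  method = method, channels = labs))
}

#' Fuse two feature tables column-wise
#'
#' Concatenates the feature columns of two tables over the same trials —
#' typically AR-parameter features with DTF network features — preserving
#' trial order.
#'
#' @param a,b [feature_table()]s with identical trial count and class
#'   labels and disjoint feature names.
#' @return a [feature_table()] with provenance kind `"fused"`.
#' @export
fuse_features <- function(a, b) {
  if (nrow(a$X) != nrow(b$X))
    stop("cannot fuse: trial counts differ", call. = FALSE)
  if (!identical(a$class_labels, b$class_labels))
    stop("cannot fuse: class labels differ", call. = FALSE)
  clash <- intersect(a$feature_names, b$feature_names)
  if (length(clash))
    stop("cannot fuse: duplicated feature names: ",
         paste(utils::head(clash, 3), collapse = ", "), call. = FALSE)
  feature_table(cbind(a$X, b$X), c(a$feature_names, b$feature_names),
                a$class_labels,
                provenance = list(kind = "fused",
                                  parts = list(a$provenance, b$provenance)))
}

#' Standardize features (z-score)
#'
#' Centres and scales every feature. When `stats` is supplied (as returned
#' by a previous call) those means and scales are applied instead — the
#' mechanism for fitting statistics on training folds only and applying
#' them to test folds, which prevents information leaking across the split.
#' Zero-variance features get unit scale, with a warning.
#'
#' @param ft a [feature_table()].
#' @param stats optional list with `mean` and `scale` vectors.
#' @return a list with `table` (standardized [feature_table()]) and
#'   `stats` (the means/scales used).
#' @export
standardize_features <- function(ft, stats = NULL) {
  if (is.null(stats)) {
    mu <- colMeans(ft$X)
    sc <- apply(ft$X, 2, stats::sd)
    if (any(sc == 0)) {
      warning(sum(sc == 0), " zero-variance feature(s); unit scale used")
      sc[sc == 0] <- 1
    }
    stats <- list(mean = mu, scale = sc)
  } else {
    if (length(stats$mean) != ncol(ft$X) || length(stats$scale) != ncol(ft$X))
      stop("standardization stats do not match the feature dimensionality",
           call. = FALSE)
  }
  Xs <- sweep(sweep(ft$X, 2, stats$mean), 2, stats$scale, "/")
  list(table = feature_table(Xs, ft$feature_names, ft$class_labels,
                             ft$provenance),
       stats = stats)
}

#' Write / read a feature table as delimited text
#'
#' Tab-separated, one row per trial, feature names in the header and the
#' class label in a leading `class` column. Round-trips to better than
#' 1e-12.
#'
#' @param ft a [feature_table()].
#' @param path file path.
#' @return `path` invisibly (write); a [feature_table()] (read).
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(class = ft$class_labels, check.names = FALSE)
  df <- cbind(df, as.data.frame(ft$X, check.names = FALSE))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  feature_table(as.matrix(df[, -1, drop = FALSE]), names(df)[-1],
                df[[1]], provenance = list(kind = "external", path = path))
}
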