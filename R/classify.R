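#' Evaluation scheme for trial classification
#'
#' Two resampling protocols are provided: stratified ten-fold
#' cross-validation repeated `n_repeats` times (the default protocol), and
#' repeated stratified 50/50 train/test splits. Both stratify by class so
#' a balanced design stays balanced within every fold.
#'
#' @param kind `"tenfold-cv"` or `"half-split-repeated"`.
#' @param n_repeats number of repetitions (default 10).
#' @param seed integer seed driving all fold assignments.
#' @param shuffle randomise trial order before folding (default `TRUE`).
#' @return an object of class `"eval_scheme"`.
#' @export
eval_scheme <- function(kind = c("tenfold-cv", "half-split-repeated"),
                        n_repeats = 10L, seed, shuffle = TRUE) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  structure(list(kind = kind, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "eval_scheme")
}

#' Build stratified fold assignments for every repeat
#'
#' Returns a list (one element per repeat) of lists of test-index vectors.
#' Folds are disjoint, cover all trials, and are stratified to within one
#' trial per class. Supplying the same folds to several [train_eval()]
#' calls pairs their accuracies exactly.
#'
#' @param class_labels per-trial labels in `{-1, +1}`.
#' @param scheme an [eval_scheme()].
#' @return a list of lists of integer index vectors.
#' @export
make_folds <- function(class_labels, scheme) {
  n <- length(class_labels)
  cls <- sort(unique(class_labels))
  if (length(cls) != 2L)
    stop("classification requires exactly two classes in the data", call. = FALSE)
  n_folds <- if (scheme$kind == "tenfold-cv") 10L else 2L
  if (scheme$kind == "tenfold-cv" && any(table(class_labels) < 10L))
    stop("ten-fold CV needs at least 10 trials per class", call. = FALSE)
  withr::with_seed(scheme$seed, {
    lapply(seq_len(scheme$n_repeats), function(r) {
      fold_id <- integer(n)
      for (cl in cls) {
        idx <- which(class_labels == cl)
        if (scheme$shuffle) idx <- sample(idx)
        fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      lapply(seq_len(n_folds), function(k) which(fold_id == k))
    })
  })
}

#' Train and evaluate a linear-kernel SVM under a resampling scheme
#'
#' For every repeat and fold: feature standardization statistics are fitted
#' on the training trials and applied to the held-out trials, a linear
#' soft-margin SVM (`y = sgn(w . x + b)`, inner-product kernel) is trained
#' on the training trials, and the held-out accuracy is recorded in
#' percent. The reported quantity is the arithmetic mean over all folds and
#' repeats.
#'
#' @param ft a [feature_table()].
#' @param scheme an [eval_scheme()].
#' @param svm_c soft-margin cost C (> 0, default 1).
#' @param folds optional precomputed fold structure from `make_folds()`;
#'   supplying the same folds to several feature sets makes their
#'   accuracies exactly paired.
#' @return an object of class `"eval_result"`: list with
#'   `per_repeat_fold_accuracy` (list of numeric vectors, percent),
#'   `mean_accuracy`, `sd_accuracy`, `scheme`, `n_features`, `n_trials`.
#' @export
train_eval <- function(ft, scheme, svm_c = 1, folds = NULL) {
  stopifnot(inherits(ft, "feature_table"), inherits(scheme, "eval_scheme"))
  if (svm_c <= 0) stop("svm_c must be positive", call. = FALSE)
  y <- ft$class_labels
  if (length(unique(y)) < 2L)
    stop("protocol error: only one class present", call. = FALSE)
  if (is.null(folds)) folds <- make_folds(y, scheme)

  acc <- lapply(folds, function(rep_folds) {
    # half-split: fold 1 trains, fold 2 tests (one accuracy per repeat)
    test_sets <- if (scheme$kind == "half-split-repeated") rep_folds[2]
    else rep_folds
    vapply(test_sets, function(test_idx) {
      if (length(test_idx) < 1L)
        stop("protocol error: empty test fold", call. = FALSE)
      train_idx <- setdiff(seq_along(y), test_idx)
      tr <- feature_table(ft$X[train_idx, , drop = FALSE], ft$feature_names,
                          y[train_idx], ft$provenance)
      te <- feature_table(ft$X[test_idx, , drop = FALSE], ft$feature_names,
                          y[test_idx], ft$provenance)
      std <- suppressWarnings(standardize_features(tr))
      te_s <- suppressWarnings(standardize_features(te, std$stats))$table
      fit <- e1071::svm(x = std$table$X,
                        y = factor(tr$class_labels, levels = c(-1L, 1L)),
                        kernel = "linear", cost = svm_c, scale = FALSE)
      pred <- stats::predict(fit, te_s$X)
      100 * mean(as.integer(as.character(pred)) == te$class_labels)
    }, 1)
  })
  all_acc <- unlist(acc)
  structure(list(per_repeat_fold_accuracy = acc,
                 mean_accuracy = mean(all_acc),
                 sd_accuracy = stats::sd(all_acc),
                 scheme = scheme, n_features = ncol(ft$X),
                 n_trials = nrow(ft$X)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s, %d repeat(s): mean accuracy %.1f%% (sd %.1f) over %d trials x %d features\n",
              x$scheme$kind, x$scheme$n_repeats, x$mean_accuracy,
              x$sd_accuracy, x$n_trials, x$n_features))
  invisible(x)
}

#' Compare feature pipelines on identical fold assignments
#'
#' Runs several feature configurations on one trial set under one
#' resampling scheme, with the fold assignments shared across
#' configurations so accuracy differences are paired. Each configuration
#' is a list with `features` in `{"ar", "dtf", "fused"}` and optional
#' fields `ar_order`, `freqs`, `mvar_order`, `include_diagonal`,
#' `montage` (applied before feature extraction).
#'
#' With the default `configs`, the comparison reproduces the standard
#' report layout: AR-only, DTF-only at each single frequency of
#' 10/15/20/25/30 Hz, and AR fused with 30 Hz DTF.
#'
#' @param ts a [trialset()].
#' @param configs named list of configurations (see details); `NULL` for
#'   the default sweep.
#' @param scheme an [eval_scheme()].
#' @param svm_c soft-margin cost (default 1).
#' @return a data frame with one row per configuration: `config`,
#'   `features`, `frequency_hz`, `montage`, `n_features`,
#'   `mean_accuracy_pct`, `sd_accuracy_pct`.
#' @export
compare_pipelines <- function(ts, configs = NULL, scheme, svm_c = 1) {
  validate_trialset(ts)
  if (is.null(configs)) {
    configs <- c(
      list(ar = list(features = "ar")),
      stats::setNames(
        lapply(c(10, 15, 20, 25, 30), function(f)
          list(features = "dtf", freqs = f)),
        paste0("dtf", c(10, 15, 20, 25, 30))),
      list(fused30 = list(features = "fused", freqs = 30)))
  }
  folds <- make_folds(ts$class_labels, scheme)

  rows <- lapply(names(configs), function(nm) {
    cfg <- configs[[nm]]
    ts_c <- if (!is.null(cfg$montage)) select_channels(ts, cfg$montage) else ts
    ar_order <- cfg$ar_order %||% 6L
    freqs <- cfg$freqs %||% c(10, 15, 20, 25, 30)
    mvar_order <- cfg$mvar_order %||% "aic"
    ft <- tryCatch(switch(
      cfg$features,
      ar = ar_features(ts_c, order = ar_order),
      dtf = dtf_features(ts_c, freqs = freqs, mvar_order = mvar_order,
                         include_diagonal = isTRUE(cfg$include_diagonal)),
      fused = fuse_features(
        ar_features(ts_c, order = ar_order),
        dtf_features(ts_c, freqs = freqs, mvar_order = mvar_order,
                     include_diagonal = isTRUE(cfg$include_diagonal))),
      stop("unknown feature kind: ", cfg$features, call. = FALSE)),
      error = function(e)
        stop(sprintf("config '%s': %s", nm, conditionMessage(e)), call. = FALSE))
    res <- train_eval(ft, scheme, svm_c = svm_c, folds = folds)
    data.frame(config = nm, features = cfg$features,
               frequency_hz = if (cfg$features != "ar" && length(freqs) == 1L)
                 freqs else NA_real_,
               montage = if (!is.null(cfg$montage)) montage(cfg$montage)$name
               else "as-is",
               n_features = res$n_features,
               mean_accuracy_pct = res$mean_accuracy,
               sd_accuracy_pct = res$sd_accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
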