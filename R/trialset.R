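#' Construct a labelled multichannel trial set
#'
#' A `trialset` is the pipeline's universal input: a collection of epoched
#' multichannel EEG trials with a sampling rate, ordered 10-20-system channel
#' labels, and a two-class label (`-1` = left, `+1` = right) per trial.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channel_labels character vector of channel names, length =
#'   `dim(data)[2]`, e.g. `c("C3", "C4")`.
#' @param class_labels integer vector of per-trial class labels in
#'   `{-1, +1}`, length = `dim(data)[1]`.
#' @param epoch_window numeric length-2, epoch start and end in seconds
#'   relative to trial onset (metadata only; default `c(NA, NA)`).
#'
#' @return An object of class `"trialset"`.
#' @examples
#' x <- array(rnorm(3 * 2 * 10), dim = c(3, 2, 10))
#' ts <- trialset(x, fs = 500, channel_labels = c("C3", "C4"),
#'                class_labels = c(-1, 1, -1))
#' @export
trialset <- function(data, fs, channel_labels, class_labels,
                     epoch_window = c(NA_real_, NA_real_)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)", call. = FALSE)
  storage.mode(data) <- "double"
  ts <- structure(
    list(data = data,
         fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         class_labels = as.integer(class_labels),
         epoch_window = as.numeric(epoch_window)),
    class = "trialset")
  validate_trialset(ts)
  ts
}

#' Validate trial-set invariants
#'
#' Checks dimensions, label lengths, class-label alphabet and finiteness.
#' Non-finite samples are reported with the offending trial and channel.
#'
#' @param ts a [trialset()].
#' @return `ts`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_trialset <- function(ts) {
  d <- dim(ts$data)
  if (d[1] < 1L) stop("trialset needs at least 1 trial", call. = FALSE)
  if (d[2] < 2L) stop("trialset needs at least 2 channels", call. = FALSE)
  if (d[3] < 2L) stop("trialset needs at least 2 samples per trial", call. = FALSE)
  if (length(ts$channel_labels) != d[2])
    stop(sprintf("channel_labels has length %d but data has %d channels",
                 length(ts$channel_labels), d[2]), call. = FALSE)
  if (anyDuplicated(ts$channel_labels))
    stop("channel_labels must be unique", call. = FALSE)
  if (length(ts$class_labels) != d[1])
    stop(sprintf("class_labels has length %d but data has %d trials",
                 length(ts$class_labels), d[1]), call. = FALSE)
  if (!all(ts$class_labels %in% c(-1L, 1L)))
    stop("class_labels must all be -1 or +1", call. = FALSE)
  if (!is.finite(ts$fs) || ts$fs <= 0)
    stop("fs must be a positive, finite sampling rate in Hz", call. = FALSE)
  if (!all(is.finite(ts$data))) {
    bad <- which(!is.finite(ts$data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite sample in trial %d, channel %s",
                 bad[1], ts$channel_labels[bad[2]]), call. = FALSE)
  }
  invisible(ts)
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("channels:", paste(x$channel_labels, collapse = " "), "\n")
  tab <- table(factor(x$class_labels, levels = c(-1L, 1L)))
  cat(sprintf("classes: %d x -1 (left), %d x +1 (right)\n", tab[1], tab[2]))
  if (all(is.finite(x$epoch_window)))
    cat(sprintf("epoch window: [%g, %g) s\n", x$epoch_window[1], x$epoch_window[2]))
  invisible(x)
}

#' Number of trials, channels and samples of a trial set
#' @param ts a [trialset()].
#' @return integer scalar.
#' @export
n_trials <- function(ts) dim(ts$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(ts) dim(ts$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(ts) dim(ts$data)[3]

## ---------------------------------------------------------------------------
## Montages

# The 32-channel layout of a standard 32-electrode 10-20 cap
.full32_labels <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")

.montage_presets <- list(
  pair2   = c("C3", "C4"),
  motor10 = c("F3", "F4", "C3", "C4", "Fz", "Cz", "FC1", "FC2", "FC5", "FC6"),
  full32  = .full32_labels)

#' Channel montages
#'
#' A montage is an ordered list of channel names to select from a trial set.
#' Three presets cover the usual comparisons: `"pair2"` (C3, C4 over the left
#' and right motor cortex), `"motor10"` (ten electrodes in or near the motor
#' area: F3, F4, C3, C4, Fz, Cz, FC1, FC2, FC5, FC6) and `"full32"` (a
#' standard 32-electrode cap). Any character vector of labels defines a
#' custom montage.
#'
#' @param x a preset name (`"pair2"`, `"motor10"`, `"full32"`) or a character
#'   vector of unique channel labels.
#' @return An object of class `"montage"` with fields `name` and `labels`.
#' @examples
#' montage("pair2")
#' montage(c("Cz", "Pz"))
#' @export
montage <- function(x) {
  if (inherits(x, "montage")) return(x)
  if (length(x) == 1L && x %in% names(.montage_presets)) {
    labels <- .montage_presets[[x]]
    name <- x
  } else {
    labels <- as.character(x)
    name <- "custom"
  }
  if (anyDuplicated(labels)) stop("montage labels must be unique", call. = FALSE)
  structure(list(name = name, labels = labels), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage %s> %s\n", x$name, paste(x$labels, collapse = " ")))
  invisible(x)
}

# case-insensitive, whitespace-stripped channel-name matching (vendor files vary)
.match_labels <- function(wanted, have) {
  norm <- function(s) tolower(gsub("\\s+", "", s))
  idx <- match(norm(wanted), norm(have))
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop(sprintf("channel(s) not present in trial set: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx
}

#' Select / reorder channels of a trial set by montage
#'
#' Returns a trial set whose channels are exactly the montage's labels, in
#' montage order. Matching is case-insensitive and whitespace-stripped.
#'
#' @param ts a [trialset()].
#' @param mont a [montage()] or anything `montage()` accepts.
#' @return a [trialset()] with `length(montage(mont)$labels)` channels.
#' @export
select_channels <- function(ts, mont) {
  mont <- montage(mont)
  idx <- .match_labels(mont$labels, ts$channel_labels)
  trialset(ts$data[, idx, , drop = FALSE], fs = ts$fs,
           channel_labels = ts$channel_labels[idx],
           class_labels = ts$class_labels,
           epoch_window = ts$epoch_window)
}

## ---------------------------------------------------------------------------
## Epoching and filtering

#' Cut a continuous multichannel recording into fixed-length epochs
#'
#' Sample indexing is half-open: an epoch covering `[start_s, end_s)` seconds
#' after an onset at `t0` takes samples `floor((t0 + start_s) * fs)` up to but
#' excluding `floor((t0 + end_s) * fs)` (0-based), so a 3-9 s window at
#' 500 Hz yields exactly 3000 samples.
#'
#' @param x numeric matrix, channels x samples (continuous recording).
#' @param fs sampling rate in Hz.
#' @param onsets_s numeric vector of trial-onset times in seconds.
#' @param start_s,end_s epoch window in seconds relative to each onset.
#' @param channel_labels channel names, length `nrow(x)`.
#' @param class_labels per-trial labels in `{-1, +1}`, length `length(onsets_s)`.
#' @return a [trialset()] with `length(onsets_s)` trials.
#' @export
epoch_continuous <- function(x, fs, onsets_s, start_s, end_s,
                             channel_labels, class_labels) {
  if (end_s <= start_s) stop("end_s must exceed start_s", call. = FALSE)
  n_len <- floor(end_s * fs) - floor(start_s * fs)
  n_tr <- length(onsets_s)
  out <- array(NA_real_, dim = c(n_tr, nrow(x), n_len))
  for (i in seq_len(n_tr)) {
    from <- floor((onsets_s[i] + start_s) * fs) + 1L   # 1-based
    to <- from + n_len - 1L
    if (from < 1L || to > ncol(x))
      stop(sprintf("epoch %d ([%g, %g) s) falls outside the recording",
                   i, onsets_s[i] + start_s, onsets_s[i] + end_s), call. = FALSE)
    out[i, , ] <- x[, from:to]
  }
  trialset(out, fs = fs, channel_labels = channel_labels,
           class_labels = class_labels, epoch_window = c(start_s, end_s))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel of every trial. This step is off by default in the pipeline:
#' classification on unfiltered data is the package's standard path, and the
#' filter is exposed for sensitivity analyses.
#'
#' @param ts a [trialset()].
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param order filter order of the underlying one-pass design (default 4).
#' @return a filtered [trialset()]; metadata unchanged.
#' @export
bandpass <- function(ts, low_hz, high_hz, order = 4L) {
  fs <- ts$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- ts$data
  for (i in seq_len(n_trials(ts)))
    for (j in seq_len(n_channels(ts)))
      out[i, j, ] <- signal::filtfilt(bf, ts$data[i, j, ])
  trialset(out, fs = fs, channel_labels = ts$channel_labels,
           class_labels = ts$class_labels, epoch_window = ts$epoch_window)
}
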