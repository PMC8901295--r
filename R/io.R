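#' Save a trial set to disk
#'
#' Two formats are supported. `"rds"` writes a single native-serialization
#' container holding the data array and all metadata; it round-trips
#' bit-exactly. `"text"` writes a directory with one tab-separated file per
#' trial (channels as columns, header row of channel labels) plus a
#' `metadata.yaml` sidecar (sampling rate, labels, classes, epoch window);
#' it round-trips to better than 1e-12 (decimal serialization).
#'
#' @param ts a [trialset()].
#' @param path output file (`"rds"`) or directory (`"text"`).
#' @param format `"rds"` or `"text"`.
#' @return `path`, invisibly.
#' @seealso [load_trialset()]
#' @export
save_trialset <- function(ts, path, format = c("rds", "text")) {
  format <- match.arg(format)
  validate_trialset(ts)
  if (format == "rds") {
    saveRDS(unclass(ts), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = ts$fs,
               channel_labels = as.list(ts$channel_labels),
               class_labels = as.list(as.integer(ts$class_labels)),
               epoch_window = as.list(ts$epoch_window),
               n_trials = n_trials(ts))
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"))
  for (i in seq_len(n_trials(ts))) {
    m <- t(ts$data[i, , , drop = TRUE])          # samples x channels
    if (n_channels(ts) == 1L) m <- matrix(m, ncol = 1L)
    df <- as.data.frame(m)
    names(df) <- ts$channel_labels
    utils::write.table(
      format(df, digits = 17, scientific = TRUE, trim = TRUE),
      file = file.path(path, sprintf("trial_%04d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a trial set from disk
#'
#' Reads the formats written by [save_trialset()] plus two continuous EEG
#' recording formats (BrainVision `.vhdr` triplets and plain EDF), which are
#' cut into epochs with `epoch_spec`.
#'
#' For continuous formats `epoch_spec` is mandatory: a list with `start_s`
#' and `end_s` (epoch window in seconds relative to each trial onset),
#' `class_labels` (one of `-1`/`+1` per trial) and either explicit `onsets_s`
#' or, for BrainVision, `marker_type` (default `"Stimulus"`) selecting which
#' markers define trial onsets.
#'
#' @param path file (rds / edf / vhdr) or directory (text format).
#' @param format `"auto"` (from the extension), `"rds"`, `"text"`,
#'   `"brainvision"` or `"edf"`.
#' @param epoch_spec epoching description for continuous formats (see above).
#' @return a [trialset()].
#' @export
load_trialset <- function(path, format = c("auto", "rds", "text", "brainvision", "edf"),
                          epoch_spec = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "text"
    else switch(tolower(tools::file_ext(path)),
                rds = "rds", vhdr = "brainvision", edf = "edf",
                stop("cannot infer format from '", path, "'; pass `format`",
                     call. = FALSE))
  }
  if (!file.exists(path) && !dir.exists(path))
    stop("file not found: ", path, call. = FALSE)

  if (format == "rds") {
    obj <- readRDS(path)
    return(trialset(obj$data, obj$fs, obj$channel_labels, obj$class_labels,
                    obj$epoch_window))
  }
  if (format == "text") {
    meta_path <- file.path(path, "metadata.yaml")
    if (!file.exists(meta_path))
      stop("text trial-set directory lacks metadata.yaml: ", path, call. = FALSE)
    meta <- yaml::read_yaml(meta_path)
    labels <- unlist(meta$channel_labels)
    n_tr <- meta$n_trials
    trials <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      f <- file.path(path, sprintf("trial_%04d.tsv", i))
      if (!file.exists(f)) stop("missing trial file: ", f, call. = FALSE)
      df <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
      if (!identical(names(df), labels))
        stop(sprintf("trial file %s: header does not match metadata labels", f),
             call. = FALSE)
      trials[[i]] <- t(as.matrix(df))            # channels x samples
    }
    ns <- unique(vapply(trials, ncol, 1L))
    if (length(ns) != 1L)
      stop("trial files have inconsistent sample counts", call. = FALSE)
    arr <- array(NA_real_, dim = c(n_tr, length(labels), ns))
    for (i in seq_len(n_tr)) arr[i, , ] <- trials[[i]]
    return(trialset(arr, meta$fs, labels, unlist(meta$class_labels),
                    unlist(meta$epoch_window)))
  }

  # continuous formats
  if (is.null(epoch_spec))
    stop("`epoch_spec` is mandatory for continuous recordings", call. = FALSE)
  rec <- if (format == "brainvision") read_brainvision(path) else read_edf(path)
  onsets <- epoch_spec$onsets_s
  if (is.null(onsets)) {
    if (format != "brainvision" || is.null(rec$markers))
      stop("epoch_spec$onsets_s is required when the recording has no markers",
           call. = FALSE)
    mtype <- epoch_spec$marker_type %||% "Stimulus"
    onsets <- rec$markers$position_s[rec$markers$type == mtype]
    if (length(onsets) == 0L)
      stop("no '", mtype, "' markers found in ", path, call. = FALSE)
  }
  epoch_continuous(rec$data, rec$fs, onsets,
                   epoch_spec$start_s, epoch_spec$end_s,
                   channel_labels = rec$channel_labels,
                   class_labels = epoch_spec$class_labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## BrainVision reader (.vhdr / .eeg / .vmrk), read-only

# parse an INI-style BrainVision header/marker file into named sections
.read_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  sections <- list(); current <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      current <- gsub("^\\[|\\]\\s*$", "", ln)
      sections[[current]] <- character()
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      sections[[current]] <- c(sections[[current]], ln)
    }
  }
  lapply(sections, function(s) {
    kv <- regmatches(s, regexpr("=", s), invert = TRUE)
    stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                    trimws(vapply(kv, `[`, "", 1L)))
  })
}

#' Read a BrainVision recording
#'
#' Minimal read-only support for the BrainVision triplet: the `.vhdr` text
#' header, the binary `.eeg` data file (INT_16 with per-channel resolution
#' scaling, or IEEE_FLOAT_32; multiplexed or vectorized orientation) and the
#' optional `.vmrk` marker file.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return a list with `data` (channels x samples matrix, physical units),
#'   `fs`, `channel_labels` and `markers` (a data frame with columns `type`,
#'   `description`, `position_s`, or `NULL`).
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("file not found: ", vhdr_path, call. = FALSE)
  hdr <- .read_ini(vhdr_path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop(vhdr_path, ": not a BrainVision header", call. = FALSE)
  key <- function(v, k) if (!is.null(v) && k %in% names(v)) v[[k]] else NULL
  n_ch <- as.integer(key(ci, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(key(ci, "SamplingInterval"))  # interval in microseconds
  orientation <- toupper(key(ci, "DataOrientation") %||% "MULTIPLEXED")
  fmt <- toupper(key(hdr[["Binary Infos"]], "BinaryFormat") %||% "INT_16")

  chans <- hdr[["Channel Infos"]]
  info <- strsplit(unname(chans[paste0("Ch", seq_len(n_ch))]), ",")
  labels <- vapply(info, `[`, "", 1L)
  resolution <- vapply(info, function(x)
    if (length(x) >= 3 && nzchar(x[3])) as.numeric(x[3]) else 1, 1)

  data_file <- file.path(dirname(vhdr_path), key(ci, "DataFile"))
  sz <- file.info(data_file)$size
  con <- file(data_file, "rb"); on.exit(close(con))
  if (fmt == "INT_16") {
    raw_vals <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  n_samp <- length(raw_vals) %/% n_ch
  raw_vals <- raw_vals[seq_len(n_samp * n_ch)]
  data <- if (orientation == "MULTIPLEXED")
    matrix(raw_vals, nrow = n_ch, ncol = n_samp)        # channel-fast
  else
    t(matrix(raw_vals, nrow = n_samp, ncol = n_ch))     # VECTORIZED: sample-fast
  data <- data * resolution

  markers <- NULL
  mf <- key(ci, "MarkerFile")
  if (!is.null(mf) && file.exists(file.path(dirname(vhdr_path), mf))) {
    mk <- .read_ini(file.path(dirname(vhdr_path), mf))[["Marker Infos"]]
    if (!is.null(mk) && length(mk)) {
      parts <- strsplit(unname(mk), ",")
      markers <- data.frame(
        type = vapply(parts, `[`, "", 1L),
        description = vapply(parts, `[`, "", 2L),
        position_s = (as.numeric(vapply(parts, `[`, "", 3L)) - 1) / fs,
        stringsAsFactors = FALSE)
    }
  }
  list(data = data, fs = fs, channel_labels = labels, markers = markers)
}

## ---------------------------------------------------------------------------
## EDF reader (plain continuous EDF, 16-bit), read-only

#' Read a plain continuous EDF recording
#'
#' Minimal read-only support for European Data Format: all ordinary signals
#' must share one sampling rate; `EDF Annotations` channels are skipped.
#' Digital values are mapped to physical units with the per-signal
#' calibration from the header.
#'
#' @param path path to the `.edf` file.
#' @return a list with `data` (channels x samples, physical units), `fs` and
#'   `channel_labels`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  num(8)                                  # header bytes
  rd(44)                                  # reserved
  n_records <- num(8)
  record_dur <- num(8)
  ns <- as.integer(num(4))

  field <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- field(16)
  field(80); field(8)                     # transducer, physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)                               # prefiltering
  spr <- as.integer(field(8))             # samples per record per signal
  field(32)                               # reserved

  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop(path, ": no ordinary signals", call. = FALSE)
  if (length(unique(spr[keep])) != 1L)
    stop(path, ": signals with differing sampling rates are not supported",
         call. = FALSE)
  fs <- spr[keep][1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  n_keep <- sum(keep)
  data <- matrix(NA_real_, nrow = n_keep, ncol = n_records * spr[keep][1])
  col0 <- 0L
  for (r in seq_len(n_records)) {
    row_i <- 0L
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (keep[s]) {
        row_i <- row_i + 1L
        data[row_i, col0 + seq_len(spr[s])] <-
          (vals - dig_min[s]) * gain[s] + phys_min[s]
      }
    }
    col0 <- col0 + spr[keep][1]
  }
  list(data = data, fs = fs, channel_labels = labels[keep])
}
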