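# Programmatic writers for tiny BrainVision / EDF fixtures (test-time only;
# the package itself is read-only for these formats).

write_brainvision_fixture <- function(dir, data, fs, labels,
                                      format = c("INT_16", "IEEE_FLOAT_32"),
                                      orientation = c("MULTIPLEXED", "VECTORIZED"),
                                      resolution = 0.1,
                                      markers = NULL) {
  format <- match.arg(format); orientation <- match.arg(orientation)
  stem <- "fixture"
  vhdr <- file.path(dir, paste0(stem, ".vhdr"))
  n_ch <- nrow(data)
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    if (!is.null(markers)) paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch), labels,
            if (format == "INT_16") format(resolution, scientific = FALSE) else ""))
  writeLines(lines, vhdr)

  vals <- if (orientation == "MULTIPLEXED") as.vector(data) else as.vector(t(data))
  con <- file(file.path(dir, paste0(stem, ".eeg")), "wb")
  if (format == "INT_16") {
    writeBin(as.integer(round(vals / resolution)), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  close(con)

  if (!is.null(markers)) {
    mlines <- c("[Common Infos]", paste0("DataFile=", stem, ".eeg"),
                "[Marker Infos]",
                sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(markers)),
                        markers$type, markers$description,
                        round(markers$position_s * fs) + 1L))
    writeLines(mlines, file.path(dir, paste0(stem, ".vmrk")))
  }
  vhdr
}

write_edf_fixture <- function(path, data, fs, labels,
                              record_seconds = 1) {
  n_ch <- nrow(data)
  spr <- as.integer(fs * record_seconds)
  n_records <- ncol(data) %/% spr
  stopifnot(n_records * spr == ncol(data))
  phys_min <- -3276.8; phys_max <- 3276.7
  dig_min <- -32768; dig_max <- 32767
  gain <- (dig_max - dig_min) / (phys_max - phys_min)

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8)); wr(pad("patient", 80)); wr(pad("recording", 80))
  wr(pad("01.01.26", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + n_ch), 8)); wr(pad("", 44))
  wr(pad(n_records, 8)); wr(pad(record_seconds, 8)); wr(pad(n_ch, 4))
  for (l in labels) wr(pad(l, 16))
  for (i in seq_len(n_ch)) wr(pad("", 80))
  for (i in seq_len(n_ch)) wr(pad("uV", 8))
  for (i in seq_len(n_ch)) wr(pad(phys_min, 8))
  for (i in seq_len(n_ch)) wr(pad(phys_max, 8))
  for (i in seq_len(n_ch)) wr(pad(dig_min, 8))
  for (i in seq_len(n_ch)) wr(pad(dig_max, 8))
  for (i in seq_len(n_ch)) wr(pad("", 80))
  for (i in seq_len(n_ch)) wr(pad(spr, 8))
  for (i in seq_len(n_ch)) wr(pad("", 32))
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(n_ch)) {
      dig <- round((data[s, cols] - phys_min) * gain + dig_min)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  close(con)
  path
}
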