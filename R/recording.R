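#' Continuous EEG recording container
#'
#' An `eeg_recording` bundles a channels-by-samples matrix of voltages (in
#' microvolts) with the sampling rate, channel labels, the current reference,
#' and an event-marker table. It is the raw input to the preprocessing chain.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param reference_label label of the reference used when the data were
#'   acquired (or last re-referenced to).
#' @param markers data frame with columns `sample` (1-based sample index)
#'   and `label` (e.g. `"S1"`, `"S2"`, `"click"`). May have zero rows.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_labels,
                          reference_label = "FCz",
                          markers = data.frame(sample = integer(),
                                               label = character())) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(rate), rate > 0)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels must match the number of data rows")
  markers <- as.data.frame(markers)
  if (!all(c("sample", "label") %in% names(markers)))
    stop("markers must have columns 'sample' and 'label'")
  if (nrow(markers) > 0 &&
      (any(markers$sample < 1) || any(markers$sample > ncol(data))))
    stop("marker sample indices must lie within the recording")
  rownames(data) <- channel_labels
  structure(list(data = data,
                 rate = rate,
                 channel_labels = as.character(channel_labels),
                 reference_label = reference_label,
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  reference:", x$reference_label, "\n")
  tab <- table(x$markers$label)
  if (length(tab))
    cat("  markers:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  invisible(x)
}

is_eog_label <- function(labels) grepl("EOG", labels, ignore.case = TRUE)

#' Write a recording in BrainVision Core format
#'
#' Writes the `.vhdr` header, `.vmrk` marker file and `.eeg` binary data file
#' (multiplexed IEEE float 32). No installed R package reads or writes this
#' format, so a minimal but standard-conforming implementation is provided.
#'
#' @param rec an [eeg_recording()].
#' @param basename path without extension; three files are written.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg  <- paste0(basename, ".eeg")
  base <- basename(basename)

  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,%s,1,µV", seq_len(nrow(rec$data)),
            rec$channel_labels, rec$reference_label))
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(rec$markers) > 0)
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$markers)) + 1L,
                        rec$markers$label, rec$markers$sample))
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: sample-major, channel-minor
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(basename)
}

#' Read a BrainVision Core recording
#'
#' Supports the subset written by [write_brainvision()]: binary multiplexed
#' IEEE float 32 or signed 16-bit data with per-channel resolutions.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  getval <- function(key) {
    m <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(m)) stop("missing header key: ", key)
    sub(paste0("^", key, "="), "", m[1])
  }
  n_chan <- as.integer(getval("NumberOfChannels"))
  rate <- 1e6 / as.numeric(getval("SamplingInterval"))
  fmt <- getval("BinaryFormat")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[`, "", 1)
  ref <- vapply(ch_parts, `[`, "", 2)[1]
  res <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  dir <- dirname(vhdr)
  eeg_path <- file.path(dir, getval("DataFile"))
  info <- file.info(eeg_path)
  size <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_samp <- as.integer(info$size / (size * n_chan))
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_chan * n_samp, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n_chan * n_samp, size = 2, signed = TRUE,
            endian = "little")
  }
  data <- matrix(raw, nrow = n_chan) * res

  mrk_path <- file.path(dir, sub("\\.eeg$", ".vmrk", getval("DataFile")))
  markers <- data.frame(sample = integer(), label = character())
  if (file.exists(mrk_path)) {
    ml <- grep("^Mk[0-9]+=Stimulus,", readLines(mrk_path, warn = FALSE),
               value = TRUE)
    if (length(ml)) {
      parts <- strsplit(sub("^Mk[0-9]+=Stimulus,", "", ml), ",")
      markers <- data.frame(
        sample = as.integer(vapply(parts, `[`, "", 2)),
        label = vapply(parts, `[`, "", 1))
    }
  }
  eeg_recording(data, rate, labels, reference_label = ref, markers = markers)
}
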