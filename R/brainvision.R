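# BrainVision (.vhdr/.eeg/.vmrk) reader and writer, plus the continuous
# recording container. The supported dialect is the common BrainAmp export:
# INT_16, multiplexed, little-endian binary with per-channel resolution.

#' Continuous multichannel EEG recording
#'
#' Container for continuous EEG: a channels x samples matrix in microvolts,
#' sampling rate, channel labels, reference label, and an event table.
#' Event onsets are 0-based sample indices in `[0, n_samples)`; the
#' BrainVision marker convention (1-based) is translated at file I/O.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param srate sampling rate (Hz), > 0.
#' @param channels character vector of channel labels (length = nrow(data)).
#' @param events data.frame with columns `type`, `onset` (0-based sample),
#'   `desc`; may be empty.
#' @param reference reference label (default "average of all channels" is
#'   not assumed; raw recordings default to "nose").
#' @return a `continuous_recording` object.
#' @export
continuous_recording <- function(data, srate, channels,
                                 events = empty_events(),
                                 reference = "nose") {
  stopifnot(is.matrix(data), srate > 0, nrow(data) == length(channels))
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    stopifnot(all(events$onset >= 0), all(events$onset < ncol(data)))
  }
  structure(
    list(
      data = data, srate = srate, channels = as.character(channels),
      events = events, reference = reference
    ),
    class = "continuous_recording"
  )
}

empty_events <- function() {
  data.frame(type = character(0), onset = integer(0), desc = character(0),
    stringsAsFactors = FALSE)
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf(
    "<continuous_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
    nrow(x$events)
  ))
  invisible(x)
}

#' Write a recording as a BrainVision triplet
#'
#' Serializes to `.vhdr` (header), `.eeg` (INT_16 little-endian multiplexed
#' binary) and `.vmrk` (markers, 1-based sample positions).
#'
#' @param recording a [continuous_recording()].
#' @param out_prefix output path prefix (without extension).
#' @param resolution_uv quantization step in microvolts per integer unit
#'   (default 0.1). Values must satisfy |v| <= 32767 * resolution.
#' @return invisibly, the three file paths.
#' @export
write_brainvision <- function(recording, out_prefix, resolution_uv = 0.1) {
  x <- recording
  stopifnot(inherits(x, "continuous_recording"))
  if (!all(is.finite(x$data))) stop("write_brainvision: non-finite samples")
  lim <- 32767 * resolution_uv
  if (max(abs(x$data)) > lim) {
    stop(sprintf(
      "write_brainvision: samples exceed representable range (+-%g uV at resolution %g uV)",
      lim, resolution_uv
    ))
  }
  base <- basename(out_prefix)
  paths <- paste0(out_prefix, c(".vhdr", ".eeg", ".vmrk"))
  nch <- nrow(x$data)

  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / x$srate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,%s,%g,µV", seq_len(nch), x$channels, x$reference,
      resolution_uv)
  )
  writeLines(hdr, paths[1], useBytes = TRUE)

  q <- as.integer(round(x$data / resolution_uv)) # multiplexed: column-major
  con <- file(paths[2], "wb")
  writeBin(q, con, size = 2, endian = "little")
  close(con)

  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(x$events) > 0) {
    mk <- c(mk, sprintf(
      "Mk%d=%s,%s,%d,1,0",
      seq_len(nrow(x$events)) + 1L, x$events$type, x$events$desc,
      as.integer(x$events$onset) + 1L
    ))
  }
  writeLines(mk, paths[3], useBytes = TRUE)
  invisible(paths)
}

parse_vhdr_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      out[[section]][[key]] <- val
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' Parses the `.vhdr` header, loads the INT_16 multiplexed `.eeg` binary
#' scaled to microvolts by the per-channel resolution, and parses `.vmrk`
#' markers into the event table (converted to 0-based onsets).
#'
#' Errors are named: `bv_missing_file`, `bv_unsupported_format`,
#' `bv_channel_mismatch`.
#'
#' @param header_path path to the `.vhdr` file.
#' @return a [continuous_recording()].
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) {
    stop("bv_missing_file: header not found: ", header_path)
  }
  ini <- parse_vhdr_ini(readLines(header_path, warn = FALSE, encoding = "UTF-8"))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (!identical(ci$DataFormat, "BINARY") ||
      !identical(ci$DataOrientation, "MULTIPLEXED") ||
      !identical(bi$BinaryFormat, "INT_16")) {
    stop("bv_unsupported_format: only BINARY/MULTIPLEXED/INT_16 is supported")
  }
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci$DataFile)
  mark_path <- file.path(dir, ci$MarkerFile)
  if (!file.exists(data_path)) {
    stop("bv_missing_file: data file not found: ", data_path)
  }
  nch <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)

  chinfo <- ini[["Channel Infos"]]
  ch_keys <- names(chinfo)[grepl("^Ch[0-9]+$", names(chinfo))]
  ch_keys <- ch_keys[order(as.integer(sub("Ch", "", ch_keys)))]
  if (length(ch_keys) != nch) {
    stop("bv_channel_mismatch: NumberOfChannels=", nch,
      " but ", length(ch_keys), " channel entries")
  }
  parts <- lapply(chinfo[ch_keys], function(v) strsplit(v, ",")[[1]])
  labels <- vapply(parts, `[`, "", 1)
  refs <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  res <- vapply(parts, function(p) {
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1
  }, 0)

  nbytes <- file.size(data_path)
  nsamp <- nbytes / (2 * nch)
  if (nsamp != floor(nsamp)) {
    stop("bv_channel_mismatch: .eeg size ", nbytes,
      " bytes is not a multiple of 2 x ", nch, " channels")
  }
  con <- file(data_path, "rb")
  raw_int <- readBin(con, "integer", n = nch * nsamp, size = 2,
    signed = TRUE, endian = "little")
  close(con)
  data <- matrix(as.numeric(raw_int), nrow = nch) * res # res recycles by row

  events <- empty_events()
  if (file.exists(mark_path)) {
    ml <- readLines(mark_path, warn = FALSE, encoding = "UTF-8")
    ml <- grep("^Mk[0-9]+=", trimws(ml), value = TRUE)
    if (length(ml) > 0) {
      fields <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      ev <- data.frame(
        type = vapply(fields, `[`, "", 1),
        onset = vapply(fields, function(f) as.integer(f[3]), 0L) - 1L,
        desc = vapply(fields, `[`, "", 2),
        stringsAsFactors = FALSE
      )
      events <- ev[ev$type != "New Segment", , drop = FALSE]
      rownames(events) <- NULL
    }
  }
  continuous_recording(data, srate, labels,
    events = events,
    reference = refs[1]
  )
}
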