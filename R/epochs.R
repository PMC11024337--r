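# Epoched recordings: trials x channels x time with trial metadata.

#' Construct an epoched recording
#'
#' @param data numeric array trials x channels x samples (microvolts).
#' @param srate sampling rate (Hz).
#' @param times time axis in ms relative to first-tone onset; strictly
#'   increasing, uniform step `1000/srate`. Windows are half-open
#'   `[start, end)` throughout the package.
#' @param channels channel labels.
#' @param info data.frame of per-trial metadata, one row per trial
#'   (columns such as trial_type, is_match, response, correct, session,
#'   subject, group).
#' @return an `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, srate, times, channels, info = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
    dim(data)[2] == length(channels))
  if (length(times) > 1) {
    dt <- diff(times)
    stopifnot(all(dt > 0), max(abs(dt - 1000 / srate)) < 1e-6)
  }
  if (is.null(info)) {
    info <- data.frame(trial = seq_len(dim(data)[1]))
  }
  stopifnot(nrow(info) == dim(data)[1])
  structure(
    list(data = data, srate = srate, times = times,
      channels = as.character(channels), info = info),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d ch x %d samples @ %g Hz, t = [%g, %g) ms\n",
    d[1], d[2], d[3], x$srate, x$times[1],
    x$times[length(x$times)] + 1000 / x$srate
  ))
  invisible(x)
}

# index of time axis samples inside the half-open window [w1, w2) ms
time_index <- function(times, window_ms) {
  which(times >= window_ms[1] & times < window_ms[2])
}

#' Cut a continuous recording into epochs
#'
#' One trial per selected event; the epoch spans the half-open window
#' `[start, end)` ms around the event onset (time 0 = event onset = first
#' tone onset in the training task). Sample values are copied unmodified.
#' Events whose window exceeds the recording edge are dropped and logged in
#' the `"dropped"` attribute.
#'
#' @param recording a [continuous_recording()].
#' @param event_type event type to epoch around (default "Stimulus").
#' @param window_ms `c(start, end)` in ms, default `c(-1000, 12000)`.
#' @param metadata optional data.frame with one row per selected event (in
#'   event order, before dropping); joined as trial info.
#' @param desc_pattern optional regex applied to the event `desc` field.
#' @return an [eeg_epochs()] object; attribute `"dropped"` lists dropped
#'   event indices.
#' @export
epoch <- function(recording, event_type = "Stimulus",
                  window_ms = c(-1000, 12000), metadata = NULL,
                  desc_pattern = NULL) {
  x <- recording
  stopifnot(inherits(x, "continuous_recording"), window_ms[2] > window_ms[1])
  ev <- x$events[x$events$type == event_type, , drop = FALSE]
  if (!is.null(desc_pattern)) {
    ev <- ev[grepl(desc_pattern, ev$desc), , drop = FALSE]
  }
  if (nrow(ev) == 0) stop("epoch: no matching events")
  if (!is.null(metadata)) stopifnot(nrow(metadata) == nrow(ev))

  spms <- x$srate / 1000
  rel <- seq(
    from = round(window_ms[1] * spms),
    length.out = round((window_ms[2] - window_ms[1]) * spms)
  )
  times <- rel / spms
  nsamp <- ncol(x$data)

  first <- ev$onset + rel[1] + 1 # 1-based first sample
  last <- ev$onset + rel[length(rel)] + 1
  keep <- first >= 1 & last <= nsamp
  dropped <- which(!keep)
  if (length(dropped) > 0) {
    message(sprintf("epoch: dropped %d event(s) too close to recording edge: %s",
      length(dropped), paste(dropped, collapse = ", ")))
  }
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) stop("epoch: all events dropped at recording edges")

  arr <- array(0, dim = c(nrow(ev), nrow(x$data), length(rel)))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$onset[i] + rel + 1
    arr[i, , ] <- x$data[, idx, drop = FALSE]
  }
  info <- if (is.null(metadata)) NULL else metadata[keep, , drop = FALSE]
  out <- eeg_epochs(arr, x$srate, times, x$channels, info)
  attr(out, "dropped") <- dropped
  out
}
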