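# Preprocessing chain: TMS pulse detection, Gaussian-noise artifact
# replacement, zero-phase band-pass filtering, FFT resampling, average
# re-referencing, and amplitude-based trial rejection.
#
# Canonical order (configurable in preprocess_chain): detect -> replace ->
# resample -> filter -> epoch -> re-reference -> reject.

#' Detect TMS pulses in a continuous recording
#'
#' Without a schedule: flags samples whose absolute amplitude exceeds
#' `threshold_sd` times the channel's robust SD (1.4826 * MAD) on any
#' channel, merges flags closer than `merge_ms`, and takes each cluster's
#' sample of maximal absolute amplitude as the pulse peak. With a schedule:
#' converts the scheduled trial-relative onsets to recording samples using
#' the "Stimulus" trial-onset events and refines each to the local absolute
#' peak (+-5 ms).
#'
#' @param recording a [continuous_recording()].
#' @param threshold_sd robust-SD multiple for flagging (default 8).
#' @param schedule optional [schedule_tms()]; trials are matched to
#'   "Stimulus" events in order.
#' @param merge_ms flags closer than this are one pulse (default 20).
#' @return a `pulse_events` object: integer 0-based peak samples with
#'   attributes `method` and `threshold_sd`.
#' @export
detect_tms_pulses <- function(recording, threshold_sd = 8, schedule = NULL,
                              merge_ms = 20) {
  x <- recording
  stopifnot(inherits(x, "continuous_recording"), ncol(x$data) > 0)
  spms <- x$srate / 1000
  if (!is.null(schedule)) {
    tr_ev <- x$events[x$events$type == "Stimulus", , drop = FALSE]
    key <- unique(schedule[c("run", "trial")])
    if (nrow(tr_ev) != nrow(key)) {
      stop("detect_tms_pulses: schedule has ", nrow(key),
        " trials but recording has ", nrow(tr_ev), " Stimulus events")
    }
    skey <- paste(schedule$run, schedule$trial)
    ukey <- paste(key$run, key$trial)
    onsets <- unlist(lapply(seq_len(nrow(tr_ev)), function(i) {
      tr_ev$onset[i] + round(schedule$onset_ms[skey == ukey[i]] * spms)
    }))
    halfw <- round(5 * spms)
    absmax <- apply(abs(x$data), 2, max) # per-sample max over channels
    peaks <- vapply(onsets, function(o) {
      lo <- max(0, o - halfw)
      hi <- min(ncol(x$data) - 1, o + halfw)
      seg <- absmax[(lo + 1):(hi + 1)]
      as.integer(lo + which.max(seg) - 1)
    }, 0L)
    method <- "scheduled"
  } else {
    med <- apply(x$data, 1, stats::median)
    rsd <- apply(x$data, 1, stats::mad) # 1.4826 * MAD
    rsd[rsd == 0] <- Inf
    over <- colSums(abs(x$data - med) > threshold_sd * rsd) > 0
    flags <- which(over) - 1L # 0-based
    if (length(flags) == 0) {
      peaks <- integer(0)
    } else {
      gap <- round(merge_ms * spms)
      brk <- c(0L, which(diff(flags) > gap))
      absmax <- apply(abs(x$data), 2, max)
      peaks <- vapply(seq_along(brk), function(k) {
        lo <- brk[k] + 1L
        hi <- if (k < length(brk)) brk[k + 1] else length(flags)
        cl <- flags[lo:hi]
        cl[which.max(absmax[cl + 1])]
      }, 0L)
    }
    method <- "threshold"
  }
  peaks <- sort(unique(as.integer(peaks)))
  structure(peaks, method = method, threshold_sd = threshold_sd,
    class = "pulse_events")
}

#' Replace TMS artifacts with matched Gaussian noise
#'
#' For each pulse peak and each channel, samples in the closed span
#' [peak - pre_ms, peak + post_ms] are replaced by independent Gaussian
#' draws whose mean and SD match that channel's reference segment
#' [peak - 35, peak - 15) ms (by default). All other samples are
#' bit-identical to the input. If a reference window overlaps a previous
#' pulse's replacement span, the nearest earlier clean window of equal
#' length is used and the shift is logged in the `"ref_shifted"` attribute.
#'
#' @param recording a [continuous_recording()].
#' @param pulses a [detect_tms_pulses()] result (0-based peak samples).
#' @param pre_ms,post_ms replacement span around the peak (default 10/20).
#' @param ref_window_ms reference window relative to the peak, half-open
#'   (default c(-35, -15)).
#' @param seed integer seed for the Gaussian draws.
#' @return the recording with replaced spans; attribute `"ref_shifted"`
#'   lists pulses whose reference window was moved.
#' @export
replace_tms_artifacts <- function(recording, pulses, pre_ms = 10,
                                  post_ms = 20,
                                  ref_window_ms = c(-35, -15),
                                  seed = NULL) {
  x <- recording
  stopifnot(inherits(x, "continuous_recording"))
  if (length(pulses) == 0) return(x)
  spms <- x$srate / 1000
  n <- ncol(x$data)
  nch <- nrow(x$data)
  pre <- round(pre_ms * spms)
  post <- round(post_ms * spms)
  rw <- round(ref_window_ms * spms)
  rlen <- rw[2] - rw[1]
  shifted <- integer(0)
  prev_span_end <- -Inf # 0-based end of the previous replacement span
  with_seed(seed, {
    for (p in as.integer(pulses)) {
      r0 <- p + rw[1]
      r1 <- p + rw[2] # half-open [r0, r1)
      if (r0 < 0) stop("replace_tms_artifacts: reference window before start")
      if (r0 <= prev_span_end) {
        # slide the window left of the previous replacement span
        shift_to <- prev_span_end - rlen - round(5 * spms)
        r0 <- max(0, shift_to)
        r1 <- r0 + rlen
        shifted <- c(shifted, p)
      }
      s0 <- max(0, p - pre)
      s1 <- min(n - 1, p + post) # closed span
      ref <- x$data[, (r0 + 1):r1, drop = FALSE]
      mu <- rowMeans(ref)
      sdv <- apply(ref, 1, stats::sd)
      len <- s1 - s0 + 1
      repl <- matrix(stats::rnorm(nch * len), nch, len) * sdv + mu
      x$data[, (s0 + 1):(s1 + 1)] <- repl
      prev_span_end <- s1
    }
  })
  attr(x, "ref_shifted") <- shifted
  x
}

#' Zero-phase band-pass filter
#'
#' Hamming-windowed-sinc FIR applied forward-backward (zero phase). The DC
#' gain is exactly zero for a band-pass design; pass-band ripple is below
#' 1%.
#'
#' @param x a [continuous_recording()] or [eeg_epochs()].
#' @param low_hz,high_hz corner frequencies (defaults 0.3 and 50).
#' @param trans_hz optional transition width override (Hz).
#' @return the filtered object.
#' @export
bandpass_filter <- function(x, low_hz = 0.3, high_hz = 50, trans_hz = NULL) {
  if (!is.null(low_hz) && !is.null(high_hz) && low_hz >= high_hz) {
    stop("bandpass_filter: band edges inverted")
  }
  apply_channels(x, function(mat, srate) {
    if (!is.null(high_hz) && high_hz >= srate / 2) {
      stop("bandpass_filter: high_hz must be below Nyquist")
    }
    h <- fir_design(low_hz, high_hz, srate, trans_hz)
    filtfilt_fir(mat, h)
  })
}

# apply f(samples x channels matrix, srate) over a recording or epochs
apply_channels <- function(x, f) {
  if (inherits(x, "continuous_recording")) {
    x$data <- t(f(t(x$data), x$srate))
    x
  } else if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    for (i in seq_len(d[1])) {
      x$data[i, , ] <- t(f(t(x$data[i, , ]), x$srate))
    }
    x
  } else {
    stop("unsupported input")
  }
}

#' Resample a recording (anti-aliased FFT method)
#'
#' Spectrum-truncation resampling; event onsets are rescaled and rounded to
#' the nearest new sample; total duration is preserved within one sample.
#'
#' @param x a [continuous_recording()] or [eeg_epochs()].
#' @param target_hz target rate (0 < target_hz <= current rate).
#' @return the resampled object.
#' @export
resample_recording <- function(x, target_hz = 500) {
  if (target_hz <= 0) stop("resample_recording: target rate must be > 0")
  if (inherits(x, "continuous_recording")) {
    if (target_hz > x$srate) stop("resample_recording: upsampling not supported")
    if (target_hz == x$srate) return(x)
    n_new <- round(ncol(x$data) * target_hz / x$srate)
    x$data <- t(fft_resample(t(x$data), n_new))
    if (nrow(x$events) > 0) {
      x$events$onset <- pmin(
        n_new - 1L,
        as.integer(round(x$events$onset * target_hz / x$srate))
      )
    }
    x$srate <- target_hz
    x
  } else if (inherits(x, "eeg_epochs")) {
    if (target_hz > x$srate) stop("resample_recording: upsampling not supported")
    if (target_hz == x$srate) return(x)
    d <- dim(x$data)
    n_new <- round(d[3] * target_hz / x$srate)
    arr <- array(0, dim = c(d[1], d[2], n_new))
    for (i in seq_len(d[1])) {
      arr[i, , ] <- t(fft_resample(t(x$data[i, , ]), n_new))
    }
    times <- x$times[1] + (seq_len(n_new) - 1) * 1000 / target_hz
    eeg_epochs(arr, target_hz, times, x$channels, x$info)
  } else {
    stop("unsupported input")
  }
}

#' Re-reference to the average of all channels
#'
#' Subtracts the per-sample mean over scalp channels; the resulting mean
#' over channels is identically zero.
#'
#' @param x a [continuous_recording()] or [eeg_epochs()].
#' @return the re-referenced object.
#' @export
rereference_average <- function(x) {
  if (inherits(x, "continuous_recording")) {
    stopifnot(nrow(x$data) >= 2)
    x$data <- sweep(x$data, 2, colMeans(x$data))
    x$reference <- "average"
    x
  } else if (inherits(x, "eeg_epochs")) {
    stopifnot(dim(x$data)[2] >= 2)
    m <- apply(x$data, c(1, 3), mean)
    x$data <- x$data - aperm(
      array(m, dim = dim(x$data)[c(1, 3, 2)]), c(1, 3, 2)
    )
    x
  } else {
    stop("unsupported input")
  }
}

#' Reject trials on absolute amplitude
#'
#' A trial is dropped iff any channel contains a sample with
#' `|value| > threshold_uv` anywhere in the epoch window (strict
#' inequality: a sample exactly at the threshold is kept).
#'
#' @param epochs an [eeg_epochs()].
#' @param threshold_uv threshold in microvolts (default 250).
#' @return list with elements `epochs` (kept trials) and `log`
#'   (data.frame: trial, kept, channel, peak_uv). If everything is
#'   rejected the empty epochs object is returned with a warning.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 250) {
  stopifnot(inherits(epochs, "eeg_epochs"), threshold_uv > 0)
  d <- dim(epochs$data)
  log <- data.frame(
    trial = seq_len(d[1]), kept = TRUE,
    channel = NA_character_, peak_uv = NA_real_
  )
  for (i in seq_len(d[1])) {
    absmax_ch <- apply(abs(epochs$data[i, , , drop = FALSE]), 2, max)
    peak <- max(absmax_ch)
    if (peak > threshold_uv) {
      log$kept[i] <- FALSE
      log$channel[i] <- epochs$channels[which.max(absmax_ch)]
      log$peak_uv[i] <- peak
    }
  }
  keep <- which(log$kept)
  if (length(keep) == 0) {
    warning("reject_amplitude: all trials rejected")
  }
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$info <- epochs$info[keep, , drop = FALSE]
  list(epochs = out, log = log)
}

#' Full preprocessing chain
#'
#' detect -> replace -> resample -> filter -> [ICA hook] -> epoch ->
#' re-reference -> reject, following the analysis narrative. The ICA
#' residual-artifact step is exposed as a pluggable hook with a
#' pass-through default (component decomposition itself is out of scope).
#'
#' @param recording a [continuous_recording()].
#' @param schedule optional [schedule_tms()]; NULL for sessions without
#'   stimulation (skips detection/replacement).
#' @param metadata optional per-trial metadata (behavior table rows in
#'   event order).
#' @param target_hz resample target (default 500).
#' @param low_hz,high_hz filter band (default 0.3-50).
#' @param window_ms epoch window (default c(-1000, 12000)).
#' @param threshold_uv rejection threshold (default 250).
#' @param ica_hook function(epochs) -> epochs, default identity.
#' @param seed seed for the artifact-replacement noise.
#' @return list: `epochs`, `rejection_log`, `pulses`, `params`.
#' @export
preprocess_chain <- function(recording, schedule = NULL, metadata = NULL,
                             target_hz = 500, low_hz = 0.3, high_hz = 50,
                             window_ms = c(-1000, 12000),
                             threshold_uv = 250,
                             ica_hook = identity, seed = NULL) {
  pulses <- NULL
  x <- recording
  if (!is.null(schedule)) {
    pulses <- detect_tms_pulses(x, schedule = schedule)
    x <- replace_tms_artifacts(x, pulses, seed = seed)
  }
  x <- resample_recording(x, target_hz)
  x <- bandpass_filter(x, low_hz, high_hz)
  ep <- epoch(x, "Stimulus", window_ms, metadata = metadata)
  ep <- ica_hook(ep)
  ep <- rereference_average(ep)
  rej <- reject_amplitude(ep, threshold_uv)
  list(
    epochs = rej$epochs, rejection_log = rej$log, pulses = pulses,
    params = list(
      target_hz = target_hz, low_hz = low_hz, high_hz = high_hz,
      window_ms = window_ms, threshold_uv = threshold_uv, seed = seed
    )
  )
}
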