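# Morlet wavelet time-frequency maps, baseline z-scoring, theta-band
# Hilbert envelopes, manipulation-window topographies, and across-subject
# power-behavior correlation maps.

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves each trial and channel with complex Morlet wavelets and
#' averages the magnitudes across trials (induced + evoked power). The
#' family is parameterized by the ratio f0/sigma_f (default 7): at center
#' frequency f0, sigma_f = f0/ratio and sigma_t = 1/(2*pi*sigma_f).
#' Convolution edges are mirror-padded; per frequency, the first and last
#' 3*sigma_t are flagged in the `edge_invalid` attribute (baseline and
#' analysis windows should be interior).
#'
#' @param epochs an [eeg_epochs()].
#' @param freqs center frequencies in Hz (default 1:80).
#' @param ratio f0/sigma_f (default 7).
#' @param decim keep every `decim`-th time sample in the output (default 1).
#' @return a `tfr_map`: list with `power` (channels x freqs x times
#'   magnitude array), `freqs`, `times`, `channels`, `normalization`
#'   ("raw"), `n_trials`.
#' @export
morlet_tfr <- function(epochs, freqs = 1:80, ratio = 7, decim = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  srate <- epochs$srate
  if (max(freqs) >= srate / 2) {
    stop("morlet_tfr: frequency above Nyquist")
  }
  d <- dim(epochs$data)
  n <- d[3]
  tsel <- seq(1, n, by = decim)
  sigma_t <- 1 / (2 * pi * freqs / ratio)
  if (min(freqs) > 0 && 6 * max(sigma_t) * srate > 2 * n) {
    warning("morlet_tfr: lowest frequency barely resolvable in this epoch")
  }
  pad <- min(n - 1, ceiling(3 * max(sigma_t) * srate))
  nfft <- next_fft_len(n + 2 * pad)
  # frequency-domain wavelet bank: FFT of each unit-energy Morlet kernel
  grid_f <- (seq_len(nfft) - 1) / nfft * srate
  bank <- matrix(0 + 0i, nfft, length(freqs))
  for (k in seq_along(freqs)) {
    st <- sigma_t[k]
    half <- min(pad, ceiling(5 * st * srate))
    tt <- (-half:half) / srate
    w <- exp(-tt^2 / (2 * st^2)) * exp(2i * pi * freqs[k] * tt)
    w <- w / sqrt(sum(Mod(w)^2)) # unit energy
    wpad <- c(w[(half + 1):(2 * half + 1)], numeric(nfft - 2 * half - 1),
      w[1:half]) # kernel centered at lag 0 (circular)
    bank[, k] <- stats::fft(wpad)
  }
  acc <- array(0, dim = c(d[2], length(freqs), length(tsel)))
  for (i in seq_len(d[1])) {
    x <- matrix(aperm(epochs$data[i, , , drop = FALSE], c(3, 2, 1)),
      n, d[2]) # n x nch
    # mirror padding
    xp <- rbind(
      x[seq(pad + 1, 2, by = -1), , drop = FALSE],
      x,
      x[seq(n - 1, n - pad, by = -1), , drop = FALSE]
    )
    xp <- rbind(xp, matrix(0, nfft - nrow(xp), ncol(xp)))
    spec <- stats::mvfft(xp)
    for (k in seq_along(freqs)) {
      conv <- stats::mvfft(spec * bank[, k], inverse = TRUE) / nfft
      mag <- Mod(conv[(pad + 1):(pad + n), , drop = FALSE])
      acc[, k, ] <- acc[, k, ] + t(mag[tsel, , drop = FALSE])
    }
  }
  power <- acc / d[1]
  times <- epochs$times[tsel]
  edge <- matrix(FALSE, length(freqs), length(tsel))
  for (k in seq_along(freqs)) {
    lim <- 3 * sigma_t[k] * 1000
    edge[k, ] <- times < epochs$times[1] + lim |
      times > epochs$times[n] - lim
  }
  structure(
    list(
      power = power, freqs = freqs, times = times,
      channels = epochs$channels, normalization = "raw",
      n_trials = d[1], ratio = ratio, srate = srate,
      sigma_t = sigma_t
    ),
    edge_invalid = edge, class = "tfr_map"
  )
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf(
    "<tfr_map> %d ch x %d freqs (%g-%g Hz) x %d times, %s (n_trials=%d)\n",
    length(x$channels), length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), x$normalization, x$n_trials
  ))
  invisible(x)
}

#' Baseline z-scoring
#'
#' Per channel (and frequency, for TFR maps), subtracts the mean and
#' divides by the SD of the baseline-window time samples. Bins with zero
#' baseline SD are set to 0 and logged in the `zero_sd_bins` attribute.
#'
#' @param x a `tfr_map` or `band_envelope`.
#' @param baseline_ms half-open baseline window, default c(-1000, 0).
#' @return the same type, z-scored (`normalization = "zscore"`).
#' @export
zscore_baseline <- function(x, baseline_ms = c(-1000, 0)) {
  UseMethod("zscore_baseline")
}

zscore_core <- function(mat, bidx) {
  # mat: bins x times
  base <- mat[, bidx, drop = FALSE]
  mu <- rowMeans(base)
  sdv <- apply(base, 1, stats::sd)
  zero <- which(sdv == 0)
  sdv[zero] <- Inf
  z <- (mat - mu) / sdv
  list(z = z, zero = zero)
}

#' @export
zscore_baseline.tfr_map <- function(x, baseline_ms = c(-1000, 0)) {
  bidx <- time_index(x$times, baseline_ms)
  if (length(bidx) < 2) stop("zscore_baseline: baseline window too short")
  d <- dim(x$power)
  flat <- matrix(x$power, d[1] * d[2], d[3])
  res <- zscore_core(flat, bidx)
  x$power <- array(res$z, dim = d)
  x$normalization <- "zscore"
  x$baseline_ms <- baseline_ms
  attr(x, "zero_sd_bins") <- res$zero
  x
}

#' @export
zscore_baseline.band_envelope <- function(x, baseline_ms = c(-1000, 0)) {
  bidx <- time_index(x$times, baseline_ms)
  if (length(bidx) < 2) stop("zscore_baseline: baseline window too short")
  res <- zscore_core(x$envelope, bidx)
  x$envelope <- res$z
  x$normalization <- "zscore"
  x$baseline_ms <- baseline_ms
  attr(x, "zero_sd_bins") <- res$zero
  x
}

#' Band-limited Hilbert envelope and window topography
#'
#' Zero-phase band-pass (4-8 Hz theta by default) and analytic-signal
#' magnitude per trial, averaged over trials, then (by default) z-scored
#' against the pre-stimulus baseline and averaged over the manipulation
#' window to a per-channel topography.
#'
#' @param epochs an [eeg_epochs()].
#' @param band c(low, high) Hz, default c(4, 8).
#' @param zscore z-score against baseline (default TRUE).
#' @param baseline_ms baseline window (default c(-1000, 0)).
#' @param window_ms topography averaging window (default c(5000, 10000)).
#' @param trans_hz FIR transition width (default 2 Hz).
#' @return a `band_envelope`: list with `envelope` (channels x times),
#'   `topography` (named per-channel scalar over `window_ms`), `band`,
#'   `times`, `channels`, `normalization`, `n_trials`.
#' @export
band_envelope <- function(epochs, band = c(4, 8), zscore = TRUE,
                          baseline_ms = c(-1000, 0),
                          window_ms = c(5000, 10000), trans_hz = 2) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (band[2] + trans_hz >= epochs$srate / 2) {
    stop("band_envelope: band too close to Nyquist")
  }
  d <- dim(epochs$data)
  # batch all trials x channels into one FFT pass (columns = ch x trial)
  x <- matrix(aperm(epochs$data, c(3, 2, 1)), d[3], d[2] * d[1])
  env <- band_env_core(x, epochs$srate, band, trans_hz)
  acc <- t(rowMeans(array(env, dim = c(d[3], d[2], d[1])), dims = 2))
  out <- structure(
    list(
      envelope = acc, band = band, times = epochs$times,
      channels = epochs$channels, normalization = "raw", n_trials = d[1],
      window_ms = window_ms
    ),
    class = "band_envelope"
  )
  if (zscore) out <- zscore_baseline(out, baseline_ms)
  widx <- time_index(out$times, window_ms)
  out$topography <- stats::setNames(
    rowMeans(out$envelope[, widx, drop = FALSE]), out$channels
  )
  out
}

#' @export
print.band_envelope <- function(x, ...) {
  cat(sprintf(
    "<band_envelope> %g-%g Hz, %d ch x %d times, %s (n_trials=%d)\n",
    x$band[1], x$band[2], length(x$channels), length(x$times),
    x$normalization, x$n_trials
  ))
  invisible(x)
}

#' Across-subject power-behavior correlation map
#'
#' Pearson correlation, across subjects, between per-subject time-frequency
#' maps (or topographies) and a per-subject behavioral score (d'), computed
#' independently at every bin.
#'
#' @param subject_maps list of per-subject arrays/matrices/vectors of
#'   identical shape (e.g. `tfr_map$power` arrays or topography vectors).
#' @param behavior numeric vector of per-subject scores (same length and
#'   order as `subject_maps`).
#' @return a `correlation_map`: list with `r` (array shaped like one map),
#'   `n`, `peak` (max r value and its flat index/dimension index).
#' @export
tf_behavior_correlation <- function(subject_maps, behavior) {
  n <- length(subject_maps)
  if (n < 3) stop("tf_behavior_correlation: need >= 3 subjects")
  if (length(behavior) != n) {
    stop("tf_behavior_correlation: behavior length != number of maps")
  }
  if (stats::sd(behavior) == 0) {
    stop("tf_behavior_correlation: behavior has zero variance")
  }
  shp <- dim(subject_maps[[1]])
  if (is.null(shp)) shp <- length(subject_maps[[1]])
  flat <- t(vapply(subject_maps, function(m) {
    stopifnot(identical(if (is.null(dim(m))) length(m) else dim(m), shp))
    as.numeric(m)
  }, numeric(prod(shp)))) # subjects x bins
  sds <- apply(flat, 2, stats::sd)
  r <- rep(NA_real_, ncol(flat))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(behavior, flat[, ok, drop = FALSE]))
  rarr <- if (length(shp) > 1) array(r, dim = shp) else r
  peak_idx <- which.max(abs(r))
  structure(
    list(
      r = rarr, n = n,
      peak = list(
        r = r[peak_idx],
        index = if (length(shp) > 1) arrayInd(peak_idx, shp) else peak_idx
      )
    ),
    class = "correlation_map"
  )
}
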