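# Low-level signal primitives shared across the package. Everything is built
# on stats::fft / stats::mvfft; no external DSP dependency exists on the
# target platform, and the preprocessing contract (zero-phase FIR, FFT
# resampling, analytic signal) is small enough to own.

#' Derive a child seed from a master seed
#'
#' Deterministic integer hashing so that every stochastic stage of a study
#' traces back to one master seed. Results stay below 2^31 - 1.
#'
#' @param seed master seed (integer-like scalar).
#' @param ... further integer-like scalars identifying the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (p in parts) {
    # 48271: MINSTD multiplier; cheap avalanche good enough for stream splits
    h <- (h * 48271 + (p %% m) + 11) %% m
  }
  as.integer(h)
}

#' Local RNG scope
#'
#' Runs `expr` under `set.seed(seed)` without disturbing the caller's RNG
#' state. A `NULL` seed leaves the global stream untouched.
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Smallest highly-composite FFT length >= n (stats::nextn with bases 2,3,5).
next_fft_len <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Windowed-sinc FIR band-pass kernel
#'
#' Hamming-windowed sinc design. The kernel is the difference of two
#' unity-DC-gain low-pass kernels, so the DC gain of a band-pass design is
#' exactly zero and the pass-band gain is within 1% of unity.
#'
#' @param low_hz lower corner (Hz); 0 or NULL for a pure low-pass.
#' @param high_hz upper corner (Hz); NULL for a pure high-pass.
#' @param srate sampling rate in Hz.
#' @param trans_hz transition width(s) in Hz; scalar or c(low, high). Default
#'   is the narrower of corner/2 and 2 Hz on each side.
#' @return numeric vector of odd length (symmetric, linear phase).
#' @export
fir_design <- function(low_hz, high_hz, srate, trans_hz = NULL) {
  nyq <- srate / 2
  has_low <- !is.null(low_hz) && !is.na(low_hz) && low_hz > 0
  has_high <- !is.null(high_hz) && !is.na(high_hz) && high_hz < nyq
  if (!has_low && !has_high) stop("fir_design: nothing to do (all-pass)")
  if (has_low && has_high && low_hz >= high_hz) {
    stop("fir_design: band edges inverted (low_hz >= high_hz)")
  }
  if (is.null(trans_hz)) {
    trans_hz <- c(
      if (has_low) min(max(low_hz, 0.1), 2) else NA,
      if (has_high) min(max(high_hz / 4, 0.5), 12.5) else NA
    )
  }
  trans_hz <- rep(trans_hz, length.out = 2)
  # Hamming window: transition width ~ 3.3 / N (normalized frequency)
  width <- min(trans_hz, na.rm = TRUE)
  ntaps <- ceiling(3.3 / (width / srate))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  k <- -m:m
  win <- 0.54 + 0.46 * cos(pi * k / m)
  lp <- function(fc) {
    h <- 2 * fc / srate * sinc(2 * fc / srate * k) * win
    h / sum(h) # unit DC gain
  }
  if (has_low && has_high) {
    lp(high_hz) - lp(low_hz)
  } else if (has_high) {
    lp(high_hz)
  } else {
    h <- -lp(low_hz)
    h[m + 1] <- h[m + 1] + 1 # spectral inversion -> high-pass
    h
  }
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR filtering
#'
#' Applies a symmetric FIR kernel forward and backward (filtfilt-style) via
#' FFT overlap-free convolution with edge reflection padding. The effective
#' response is |H|^2: zero phase, doubled stop-band attenuation.
#'
#' @param x numeric vector, or matrix with signals in columns.
#' @param h FIR kernel from [fir_design()].
#' @return filtered data, same shape as `x`.
#' @export
filtfilt_fir <- function(x, h) {
  if (is.matrix(x)) {
    n <- nrow(x)
  } else {
    n <- length(x)
  }
  m <- (length(h) - 1) / 2
  pad <- min(3 * m + 1, n - 1)
  nfft <- next_fft_len(n + 2 * pad + length(h))
  # |H|^2 on the nfft grid: real and >= 0 -> exactly zero phase
  hsq <- Mod(stats::fft(c(h, numeric(nfft - length(h)))))^2
  refl_pad_apply(x, n, pad, nfft, hsq)
}

# shared core: reflect-pad columns, multiply spectrum by real weights, trim
refl_pad_apply <- function(x, n, pad, nfft, w, modulus = FALSE) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  xp <- matrix(0, nfft, ncol(x))
  # odd (anti-symmetric) reflection about the end points
  xp[seq_len(pad), ] <- 2 * rep(x[1, ], each = pad) -
    x[seq(pad + 1, 2, by = -1), , drop = FALSE]
  xp[pad + seq_len(n), ] <- x
  xp[pad + n + seq_len(pad), ] <- 2 * rep(x[n, ], each = pad) -
    x[seq(n - 1, n - pad, by = -1), , drop = FALSE]
  sp <- stats::mvfft(xp) * w
  y <- stats::mvfft(sp, inverse = TRUE)[(pad + 1):(pad + n), ,
    drop = FALSE] / nfft
  y <- if (modulus) Mod(y) else Re(y)
  if (vec) y[, 1] else y
}

#' Band-limited analytic-signal envelope
#'
#' Zero-phase band-pass (|H|^2 of a Hamming FIR) and Hilbert analytic-signal
#' magnitude in a single FFT pass per column.
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param srate sampling rate (Hz).
#' @param band c(low, high) in Hz.
#' @param trans_hz FIR transition width (Hz), default 2.
#' @return envelope, same shape as `x`.
#' @export
band_env_core <- function(x, srate, band, trans_hz = 2) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < srate / 2)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  h <- fir_design(band[1], band[2], srate, trans_hz)
  m <- (length(h) - 1) / 2
  pad <- min(m, n - 1)
  nfft <- next_fft_len(n + 2 * pad + length(h))
  hsq <- Mod(stats::fft(c(h, numeric(nfft - length(h)))))^2
  # analytic-signal mask: double positive freqs, zero negative freqs
  mask <- numeric(nfft)
  mask[1] <- 1
  if (nfft %% 2 == 0) {
    mask[2:(nfft / 2)] <- 2
    mask[nfft / 2 + 1] <- 1
  } else {
    mask[2:((nfft + 1) / 2)] <- 2
  }
  refl_pad_apply(x, n, pad, nfft, hsq * mask, modulus = TRUE)
}

#' Analytic signal via FFT (Hilbert transform)
#' @param x numeric vector or matrix (columns = signals).
#' @return complex analytic signal, same shape.
#' @export
hilbert_analytic <- function(x) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  mask <- numeric(n)
  mask[1] <- 1
  if (n %% 2 == 0) {
    mask[2:(n / 2)] <- 2
    mask[n / 2 + 1] <- 1
  } else {
    mask[2:((n + 1) / 2)] <- 2
  }
  if (is.matrix(x)) {
    stats::mvfft(stats::mvfft(x) * mask, inverse = TRUE) / n
  } else {
    stats::fft(stats::fft(x) * mask, inverse = TRUE) / n
  }
}

#' 1/f^beta ("pink") noise
#'
#' Gaussian noise with power spectral density proportional to 1/f^beta,
#' synthesized in the frequency domain and scaled to a target standard
#' deviation.
#'
#' @param n samples.
#' @param srate sampling rate (Hz); only sets the frequency grid.
#' @param beta spectral exponent (1 = pink). 0 gives white noise.
#' @param sd target standard deviation of the output.
#' @return numeric vector of length `n`, mean ~ 0, sd = `sd`.
#' @export
pink_noise <- function(n, srate = 1, beta = 1, sd = 1) {
  if (sd == 0) return(numeric(n))
  nf <- next_fft_len(n)
  freqs <- seq(0, nf - 1) / nf * srate
  half <- ceiling(nf / 2)
  amp <- numeric(nf)
  # amplitude ~ f^(-beta/2); skip DC
  amp[2:half] <- freqs[2:half]^(-beta / 2)
  if (nf %% 2 == 0) amp[half + 1] <- freqs[half + 1]^(-beta / 2)
  # Hermitian spectrum with random phases
  ph <- stats::runif(half - 1, 0, 2 * pi)
  sp <- complex(length.out = nf)
  sp[2:half] <- amp[2:half] * exp(1i * ph)
  if (nf %% 2 == 0) sp[half + 1] <- amp[half + 1] * sample(c(-1, 1), 1)
  sp[nf:(nf - half + 2)] <- Conj(sp[2:half])
  x <- Re(stats::fft(sp, inverse = TRUE))[1:n]
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Matrix of independent 1/f^beta noise columns
#'
#' Batched [pink_noise()]: one inverse FFT for all columns. Column j of the
#' result equals an independent noise draw; the RNG is consumed column by
#' column (phases first), so output is reproducible under a fixed seed.
#'
#' @param n samples per column.
#' @param ncols number of independent columns.
#' @inheritParams pink_noise
#' @return an `n` x `ncols` matrix, each column mean ~0 and sd = `sd`.
#' @export
pink_noise_mat <- function(n, ncols, srate = 1, beta = 1, sd = 1) {
  if (sd == 0) return(matrix(0, n, ncols))
  nf <- next_fft_len(n)
  freqs <- seq(0, nf - 1) / nf * srate
  half <- ceiling(nf / 2)
  amp <- numeric(nf)
  amp[2:half] <- freqs[2:half]^(-beta / 2)
  if (nf %% 2 == 0) amp[half + 1] <- freqs[half + 1]^(-beta / 2)
  ph <- matrix(stats::runif((half - 1) * ncols, 0, 2 * pi), half - 1, ncols)
  sp <- matrix(0 + 0i, nf, ncols)
  sp[2:half, ] <- amp[2:half] * exp(1i * ph)
  if (nf %% 2 == 0) {
    sp[half + 1, ] <- amp[half + 1] *
      sample(c(-1, 1), ncols, replace = TRUE)
  }
  sp[nf:(nf - half + 2), ] <- Conj(sp[2:half, ])
  # Parseval: sum x^2 = sum |sp|^2 / nf, deterministic given the amplitude
  # profile -> scale analytically (per-column sd is nominal, not empirical)
  ssq <- (2 * sum(amp[2:half]^2) +
    if (nf %% 2 == 0) amp[half + 1]^2 else 0) / nf
  x <- Re(stats::mvfft(sp, inverse = TRUE))[1:n, , drop = FALSE]
  x * (sd / sqrt(ssq / nf) / nf)
}

#' FFT resampling of a uniformly sampled signal
#'
#' Spectrum-truncation resampler (anti-aliased by construction), equivalent
#' to ideal low-pass interpolation for band-limited input.
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param n_new output length.
#' @return resampled data with `n_new` rows/elements.
#' @export
fft_resample <- function(x, n_new) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n_new == n) {
    return(if (vec) x[, 1] else x)
  }
  sp <- stats::mvfft(x)
  half_new <- floor(n_new / 2)
  out <- matrix(0 + 0i, n_new, ncol(x))
  keep <- min(floor(n / 2), half_new)
  out[1, ] <- sp[1, ]
  if (keep >= 1) {
    out[2:(keep + 1), ] <- sp[2:(keep + 1), ]
    out[(n_new - keep + 1):n_new, ] <- sp[(n - keep + 1):n, ]
  }
  if (n_new %% 2 == 0 && keep == half_new) {
    # split energy at the new Nyquist bin to keep the output real
    out[half_new + 1, ] <- Re(out[half_new + 1, ])
  }
  y <- Re(stats::mvfft(out, inverse = TRUE)) / n
  if (vec) y[, 1] else y
}
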