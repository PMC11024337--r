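# Synthetic multichannel EEG: 1/f background, theta bursts during the
# manipulation window on a fronto-parietal target set, and optional TMS
# artifact trains. The generator states the world the analysis chain
# assumes; its defaults are study-scale (62 ch, 1000 Hz).

DEFAULT_TARGETS <- c(
  "P7", "P5", "P3", "P1", "Pz", "CP3", "CP1", "CPz", "CP2",
  "F3", "F1", "Fz"
)

#' Simulation configuration
#'
#' @param n_channels channel count (default 62, matching the template
#'   montage).
#' @param srate sampling rate in Hz (>= 500; acquisition default 1000).
#' @param noise_sd_uv broadband 1/f noise SD per channel (uV), default 10.
#' @param noise_exponent spectral exponent beta of the 1/f^beta background.
#' @param theta_freq_hz theta source frequency (default 5, the stimulation
#'   rate).
#' @param target_channels labels carrying the theta burst (fronto-parietal
#'   default).
#' @param target_sigma_mm spatial falloff (Gaussian sigma, mm) of the theta
#'   amplitude away from the nearest target channel.
#' @param tms_amp_uv TMS artifact peak amplitude (uV), default 2000.
#' @param tms_width_ms biphasic transient width (ms), default 4.
#' @param tms_tail_ms exponential decay tail time constant (ms), default 8.
#' @param coil_channel montage label nearest the coil (artifact is strongest
#'   there), default "P3" (left intraparietal target).
#' @param blink_rate_hz rate of additive blink templates (default 0 = none).
#' @param ramp_ms raised-cosine on/off ramp of the theta burst (default 200).
#' @param seed master seed for the generator.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 62, srate = 1000, noise_sd_uv = 10,
                       noise_exponent = 1, theta_freq_hz = 5,
                       target_channels = DEFAULT_TARGETS,
                       target_sigma_mm = 30,
                       tms_amp_uv = 2000, tms_width_ms = 4, tms_tail_ms = 8,
                       coil_channel = "P3", blink_rate_hz = 0,
                       ramp_ms = 200, seed = NULL) {
  stopifnot(srate >= 500, noise_sd_uv >= 0, tms_amp_uv >= 0)
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

# Gaussian spatial falloff from the nearest channel of a label set
spatial_profile <- function(montage, labels, sigma_mm, floor = 0) {
  pos <- as.matrix(montage[c("x", "y", "z")])
  tgt <- pos[montage$label %in% labels, , drop = FALSE]
  if (nrow(tgt) == 0) stop("spatial_profile: no target channels in montage")
  d <- apply(pos, 1, function(p) {
    sqrt(min(colSums((t(tgt) - p)^2)))
  })
  floor + (1 - floor) * exp(-d^2 / (2 * sigma_mm^2))
}

# biphasic TMS artifact template (one full sine cycle + exponential tail)
tms_waveform <- function(srate, amp_uv, width_ms, tail_ms) {
  dt <- 1000 / srate
  t_bi <- seq(0, width_ms - dt / 2, by = dt)
  bi <- amp_uv * sin(2 * pi * t_bi / width_ms)
  t_tail <- seq(dt, 4 * tail_ms, by = dt)
  tail <- amp_uv * 0.25 * exp(-t_tail / tail_ms)
  c(bi, tail)
}

#' Simulate epoched EEG for one subject and session
#'
#' Epochs span [-1000, 12000) ms around the first-tone onset. Background is
#' 1/f noise per channel; manipulation trials add a theta sinusoid with
#' 200-ms raised-cosine ramps during the manipulation window
#' [5000, 10000) ms, with amplitude `theta_gain_uv` (plus
#' `entrain_gain_uv` when a pulse schedule is present and the subject is in
#' the rhTMS group) scaled by a spatial profile peaking on the target
#' channels. When a schedule is present, each pulse adds a large biphasic
#' transient on all channels, strongest near the coil.
#'
#' Noise and theta phases are drawn from seeds that do not depend on the
#' schedule, so with/without-artifact simulations of the same subject are
#' sample-identical outside the artifact waveform.
#'
#' @param profile one row of a [simulate_cohort()] table.
#' @param protocol a [build_protocol()] result.
#' @param schedule a [schedule_tms()] result, or NULL for no stimulation.
#' @param montage a [load_montage()] result; channel count must equal
#'   `config$n_channels`.
#' @param config a [sim_config()].
#' @param session session index (only recorded in metadata and used to vary
#'   the noise seed).
#' @return an [eeg_epochs()] object with protocol metadata.
#' @export
simulate_epochs <- function(profile, protocol, schedule = NULL,
                            montage = load_montage(), config = sim_config(),
                            session = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(montage) != config$n_channels) {
    stop("simulate_epochs: montage channel count != config$n_channels")
  }
  profile <- as.list(profile)
  srate <- config$srate
  spms <- srate / 1000
  times <- seq(-1000, 12000 - 1 / spms, by = 1 / spms)
  nsamp <- length(times)
  ntr <- nrow(protocol)
  nch <- nrow(montage)

  theta_sp <- spatial_profile(montage, config$target_channels,
    config$target_sigma_mm)
  is_rh <- identical(profile$group, "rhTMS")
  amp <- profile$theta_gain_uv +
    if (!is.null(schedule) && is_rh) profile$entrain_gain_uv else 0

  # raised-cosine windowed burst over the manipulation window
  burst_env <- numeric(nsamp)
  win <- time_index(times, c(5000, 10000))
  burst_env[win] <- 1
  nr <- round(config$ramp_ms * spms)
  if (nr > 1 && length(win) > 2 * nr) {
    ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    burst_env[win[seq_len(nr)]] <- ramp
    burst_env[win[seq(length(win), by = -1, length.out = nr)]] <- ramp
  }

  art <- NULL
  art_sp <- NULL
  if (!is.null(schedule)) {
    art <- tms_waveform(srate, config$tms_amp_uv, config$tms_width_ms,
      config$tms_tail_ms)
    art_sp <- spatial_profile(montage, config$coil_channel, 50, floor = 0.3)
  }

  base_seed <- derive_seed(
    if (is.null(config$seed)) profile$seed else config$seed,
    13, session
  )
  arr <- array(0, dim = c(ntr, nch, nsamp))
  for (i in seq_len(ntr)) {
    tr_seed <- derive_seed(base_seed, i)
    sig <- with_seed(tr_seed, {
      s <- pink_noise_mat(nsamp, nch, srate, config$noise_exponent,
        config$noise_sd_uv)
      if (protocol$trial_type[i] == "manipulation" && amp > 0) {
        ph <- stats::runif(1, 0, 2 * pi)
        osc <- sin(2 * pi * config$theta_freq_hz * times / 1000 + ph) *
          burst_env
        s <- s + outer(osc, amp * theta_sp)
      }
      if (config$blink_rate_hz > 0) {
        nb <- stats::rpois(1, config$blink_rate_hz * nsamp / srate)
        if (nb > 0) {
          bl_t <- sample.int(nsamp - round(0.4 * srate), nb)
          blink <- 100 * exp(-((seq_len(round(0.4 * srate)) / srate - 0.2)^2) /
            (2 * 0.05^2))
          frontality <- pmax(0, montage$y / max(montage$y))
          for (b in bl_t) {
            idx <- b + seq_along(blink) - 1
            s[idx, ] <- s[idx, ] + outer(blink, frontality)
          }
        }
      }
      s # nsamp x nch
    })
    if (!is.null(schedule)) {
      on_ms <- schedule$onset_ms[schedule$run == protocol$run[i] &
        schedule$trial == protocol$trial[i]]
      for (o in on_ms) {
        j0 <- which.min(abs(times - o))
        idx <- j0 + seq_along(art) - 1
        ok <- idx <= nsamp
        sig[idx[ok], ] <- sig[idx[ok], ] + outer(art[ok], art_sp)
      }
    }
    arr[i, , ] <- t(sig)
  }
  info <- data.frame(
    subject = profile$subject, group = profile$group, session = session,
    run = protocol$run, trial = protocol$trial,
    trial_type = protocol$trial_type, cue = protocol$cue,
    is_match = protocol$is_match, stringsAsFactors = FALSE
  )
  eeg_epochs(arr, srate, times, montage$label, info)
}

#' Assemble a continuous recording from simulated epochs
#'
#' Concatenates trials with an inter-trial gap of 1/f noise and writes
#' "Stimulus" markers at each first-tone onset (plus "TMS" markers at pulse
#' onsets when a schedule is given). Used by the `simulate` CLI stage to
#' produce BrainVision files that the preprocessing chain can epoch back.
#'
#' @param epochs an [eeg_epochs()] from [simulate_epochs()].
#' @param schedule optional [schedule_tms()] matching the epochs' protocol.
#' @param gap_ms silence (noise-free zero) gap between trials, default 1000.
#' @return a [continuous_recording()].
#' @export
epochs_to_recording <- function(epochs, schedule = NULL, gap_ms = 1000) {
  d <- dim(epochs$data)
  spms <- epochs$srate / 1000
  pre <- round(-epochs$times[1] * spms) # samples before tone onset
  gap <- round(gap_ms * spms)
  step <- d[3] + gap
  total <- d[1] * step
  data <- matrix(0, d[2], total)
  onsets <- integer(d[1])
  for (i in seq_len(d[1])) {
    at <- (i - 1) * step
    data[, at + seq_len(d[3])] <- epochs$data[i, , ]
    onsets[i] <- at + pre # 0-based sample of tone onset
  }
  ev <- data.frame(
    type = "Stimulus",
    onset = onsets,
    desc = sprintf("S%d", seq_len(d[1])),
    stringsAsFactors = FALSE
  )
  if (!is.null(schedule)) {
    key <- paste(epochs$info$run, epochs$info$trial)
    skey <- paste(schedule$run, schedule$trial)
    tms_on <- unlist(lapply(seq_len(d[1]), function(i) {
      onsets[i] + round(schedule$onset_ms[skey == key[i]] * spms)
    }))
    ev <- rbind(ev, data.frame(
      type = "TMS", onset = tms_on,
      desc = "pulse", stringsAsFactors = FALSE
    ))
    ev <- ev[order(ev$onset), ]
  }
  continuous_recording(data, epochs$srate, epochs$channels, events = ev)
}
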