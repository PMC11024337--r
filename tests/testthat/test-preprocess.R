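# Preprocessing chain: pulse detection, artifact replacement, filtering,
# resampling, re-referencing, rejection.

noise_rec <- function(nch = 2, n = 20000, srate = 1000, sd = 10, seed = 1,
                      events = NULL) {
  rec <- with_seed(seed, continuous_recording(
    t(pink_noise_mat(n, nch, srate, 1, sd)), srate,
    paste0("ch", seq_len(nch)),
    events = if (is.null(events)) {
      data.frame(type = character(0), onset = integer(0),
        desc = character(0))
    } else events
  ))
  rec
}

test_that("detect_tms_pulses: no pulses in pure noise, planted transients
           recovered, nearby flags merged", {
  rec <- noise_rec(seed = 2)
  expect_length(detect_tms_pulses(rec, threshold_sd = 8), 0)

  planted <- sort(sample(2000:18000, 10))
  rec2 <- rec
  for (p in planted) rec2$data[, p + 1] <- 20 * 10 # ~20x robust SD
  det <- detect_tms_pulses(rec2, threshold_sd = 8)
  expect_equal(as.integer(det), planted)
  expect_equal(attr(det, "method"), "threshold")

  # two transients 5 ms apart merge into one onset
  rec3 <- rec
  rec3$data[, 5001] <- 300
  rec3$data[, 5006] <- 250
  det3 <- detect_tms_pulses(rec3, threshold_sd = 8)
  expect_length(det3, 1)
  expect_equal(as.integer(det3), 5000)
})

test_that("replace_tms_artifacts touches only the replacement spans and
           matches reference statistics", {
  rec <- noise_rec(seed = 3)
  expect_identical(replace_tms_artifacts(rec,
    structure(integer(0), class = "pulse_events")), rec)

  pulses <- structure(c(5000L, 9000L), class = "pulse_events")
  out <- replace_tms_artifacts(rec, pulses, seed = 4)
  touched <- c(4990:5020, 8990:9020) + 1
  expect_identical(out$data[, -touched], rec$data[, -touched])
  expect_false(identical(out$data[, touched], rec$data[, touched]))

  # degenerate constant reference -> constant replacement
  recc <- rec
  recc$data[1, (5000 - 35):(5000 - 15) + 1] <- 7
  outc <- replace_tms_artifacts(recc, structure(5000L,
    class = "pulse_events"), seed = 5)
  expect_true(all(outc$data[1, 4990:5020 + 1] == 7))

  # replaced-span mean/SD converge to reference stats over many pulses
  many <- structure(as.integer(seq(1000, 19000, by = 200)),
    class = "pulse_events")
  outm <- replace_tms_artifacts(rec, many, seed = 6)
  spans <- unlist(lapply(as.integer(many), function(p) (p - 10):(p + 20)))
  repl <- outm$data[1, spans + 1]
  refs <- unlist(lapply(as.integer(many), function(p) (p - 35):(p - 16)))
  ref <- rec$data[1, refs + 1]
  se <- stats::sd(ref) / sqrt(length(repl))
  expect_lt(abs(mean(repl) - mean(ref)), 4 * se)
  expect_lt(abs(stats::sd(repl) / stats::sd(ref) - 1), 0.15)
})

test_that("bandpass_filter: passband flat, stopband attenuated, DC removed", {
  t <- seq(0, 20, by = 1 / 500)
  n <- length(t)
  mk <- function(v) continuous_recording(matrix(v, 1), 500, "a")
  mid <- 3000:7000
  y5 <- bandpass_filter(mk(sin(2 * pi * 5 * t)))$data[1, ]
  expect_lt(abs(max(abs(y5[mid])) - 1), 0.01)
  y80 <- bandpass_filter(mk(sin(2 * pi * 80 * t)))$data[1, ]
  expect_lt(20 * log10(max(abs(y80[mid]))), -20)
  ydc <- bandpass_filter(mk(rep(100, n)))$data[1, ]
  expect_lt(abs(mean(ydc[mid])), 0.5)
  expect_error(bandpass_filter(mk(sin(t)), 50, 0.3), "inverted")
  expect_error(bandpass_filter(mk(sin(t)), 0.3, 400), "Nyquist")
})

test_that("resample_recording: length arithmetic, identity, amplitude
           preservation, event rescaling", {
  ev <- data.frame(type = "Stimulus", onset = c(1000L, 6001L), desc = "S")
  t <- seq(0, 12.999, by = 1e-3)
  rec <- continuous_recording(matrix(sin(2 * pi * 5 * t), 1), 1000, "a",
    events = ev)
  expect_equal(ncol(rec$data), 13000)
  r <- resample_recording(rec, 500)
  expect_equal(ncol(r$data), 6500)
  expect_equal(r$srate, 500)
  expect_equal(r$events$onset, c(500L, 3000L)) # rounded to nearest
  expect_lt(abs(max(abs(r$data[1, 1000:5000])) - 1), 0.01)
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(rec, 0), "> 0")
  expect_error(resample_recording(rec, 2000), "upsampling")
})

test_that("rereference_average zeroes the channel mean exactly", {
  arr <- array(stats::rnorm(5 * 4 * 100), dim = c(5, 4, 100))
  ep <- eeg_epochs(arr, 500, seq(0, by = 2, length.out = 100),
    paste0("c", 1:4))
  rr <- rereference_average(ep)
  expect_lt(max(abs(apply(rr$data, c(1, 3), mean))), 1e-12)
  # two channels +1/-1 already average-referenced
  ep2 <- eeg_epochs(array(rep(c(1, -1), each = 1, times = 100),
    dim = c(1, 2, 100)), 500, seq(0, by = 2, length.out = 100), c("a", "b"))
  ep2$data[1, 1, ] <- 1
  ep2$data[1, 2, ] <- -1
  expect_equal(rereference_average(ep2)$data, ep2$data)
})

test_that("reject_amplitude uses a strict +-threshold bound and logs
           offenders", {
  arr <- array(0, dim = c(3, 2, 50))
  arr[1, 1, 10] <- 249
  arr[2, 2, 20] <- 300
  arr[3, 1, 30] <- 250 # exactly at threshold: kept
  ep <- eeg_epochs(arr, 500, seq(0, by = 2, length.out = 50), c("a", "b"))
  res <- reject_amplitude(ep, 250)
  expect_equal(res$log$kept, c(TRUE, FALSE, TRUE))
  expect_equal(res$log$channel[2], "b")
  expect_equal(res$log$peak_uv[2], 300)
  expect_equal(dim(res$epochs$data)[1], 2)
  # all rejected -> warning, empty result
  arr2 <- array(400, dim = c(2, 2, 10))
  ep2 <- eeg_epochs(arr2, 500, seq(0, by = 2, length.out = 10), c("a", "b"))
  expect_warning(res2 <- reject_amplitude(ep2, 250), "all trials")
  expect_equal(dim(res2$epochs$data)[1], 0)
})

test_that("chain without pulses reduces to resample+filter (theta power
           within 5%)", {
  m <- line_montage(2)
  cfg <- sim_config(n_channels = 2, srate = 1000, noise_sd_uv = 8,
    target_channels = "ch1", coil_channel = "ch1", seed = 7)
  proto <- build_protocol(1, 2, 0, seed = 7)
  prof <- list(subject = "S01", group = "sham", base_dprime_manip = 1.7,
    base_dprime_simple = 2.9, slope = 0, slope_simple = 0,
    theta_gain_uv = 6, entrain_gain_uv = 0, seed = 8L)
  ep <- simulate_epochs(prof, proto, NULL, m, cfg)
  rec <- epochs_to_recording(ep)
  full <- preprocess_chain(rec, schedule = NULL, seed = 9)
  manual <- bandpass_filter(resample_recording(rec, 500))
  ep_manual <- rereference_average(epoch(manual, "Stimulus"))
  w <- which(full$epochs$times >= 5000 & full$epochs$times < 10000)
  p_full <- oracle_band_power(full$epochs$data[1, 1, w], 500, 4, 8)
  p_manual <- oracle_band_power(ep_manual$data[1, 1, w], 500, 4, 8)
  expect_lt(abs(p_full / p_manual - 1), 0.05)
})
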