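# Morlet TFR, baseline z-scoring, band envelope, correlation maps.

test_that("Morlet family arithmetic and spectral peak are exact", {
  # sigma_f = f0/ratio; sigma_t = 1/(2 pi sigma_f)
  f0 <- 5
  sigma_f <- f0 / 7
  sigma_t <- 1 / (2 * pi * sigma_f)
  expect_equal(sigma_f, 0.714286, tolerance = 1e-6)
  expect_equal(sigma_t, 0.222817, tolerance = 1e-6)

  ep <- toy_epochs(1, 1, 4000, 500,
    fill = function(i, ch, tt) sin(2 * pi * 5 * tt))
  tfr <- morlet_tfr(ep, freqs = 1:20, decim = 4)
  avg <- apply(tfr$power[1, , ], 1, mean)
  expect_equal(tfr$freqs[which.max(avg)], 5)
  expect_error(morlet_tfr(ep, freqs = c(5, 300)), "Nyquist")
})

test_that("Morlet magnitude: averaging identity, sign-flip invariance,
           linear amplitude scaling", {
  base <- function(tt) sin(2 * pi * 6 * tt) + 0.3 * sin(2 * pi * 11 * tt)
  ep1 <- toy_epochs(1, 1, 2000, 500, fill = function(i, ch, tt) base(tt))
  ep2 <- toy_epochs(2, 1, 2000, 500, fill = function(i, ch, tt) base(tt))
  t1 <- morlet_tfr(ep1, freqs = 4:12, decim = 4)
  t2 <- morlet_tfr(ep2, freqs = 4:12, decim = 4)
  expect_equal(t2$power, t1$power, tolerance = 1e-10)

  epf <- toy_epochs(1, 1, 2000, 500, fill = function(i, ch, tt) -base(tt))
  tf <- morlet_tfr(epf, freqs = 4:12, decim = 4)
  expect_equal(tf$power, t1$power, tolerance = 1e-10)

  epa <- toy_epochs(1, 1, 2000, 500,
    fill = function(i, ch, tt) 3 * base(tt))
  ta <- morlet_tfr(epa, freqs = 4:12, decim = 4)
  expect_equal(ta$power, 3 * t1$power, tolerance = 1e-10)
})

test_that("zscore_baseline normalizes the baseline window and handles
           degenerate SD", {
  set.seed(10)
  n <- 1000
  times <- seq(-500, by = 2, length.out = n)
  mk_map <- function(vals) {
    structure(
      list(power = array(vals, dim = c(2, 3, n)), freqs = 1:3,
        times = times, channels = c("a", "b"), normalization = "raw",
        n_trials = 1),
      class = "tfr_map"
    )
  }
  # baseline N(mu, sigma); signal window at mu + 2 sigma -> z ~ 2
  vals <- array(stats::rnorm(2 * 3 * n, 5, 2), dim = c(2, 3, n))
  sigw <- times >= 0
  vals[, , sigw] <- 5 + 2 * 2
  z <- zscore_baseline(mk_map(vals), c(-500, 0))
  bidx <- times < 0
  expect_lt(max(abs(apply(z$power[, , bidx], c(1, 2), mean))), 0.2)
  expect_lt(max(abs(apply(z$power[, , sigw], c(1, 2), mean) - 2)), 0.3)

  const <- mk_map(array(7, dim = c(2, 3, n)))
  zc <- zscore_baseline(const, c(-500, 0))
  expect_true(all(zc$power == 0))
  expect_length(attr(zc, "zero_sd_bins"), 6)
})

test_that("band_envelope recovers tone amplitude, rejects stopband, and
           contrasts planted windows", {
  # constant-envelope 6 Hz tone: envelope ~ A in the interior
  A <- 3.7
  ep <- toy_epochs(1, 1, 5000, 500,
    fill = function(i, ch, tt) A * sin(2 * pi * 6 * tt))
  env <- band_envelope(ep, zscore = FALSE)
  mid <- 1000:4000
  expect_lt(max(abs(env$envelope[1, mid] - A)) / A, 0.02)

  # 20 Hz tone: theta envelope >= 20 dB below the 6 Hz case
  ep20 <- toy_epochs(1, 1, 5000, 500,
    fill = function(i, ch, tt) A * sin(2 * pi * 20 * tt))
  env20 <- band_envelope(ep20, zscore = FALSE)
  expect_lt(mean(env20$envelope[1, mid]), mean(env$envelope[1, mid]) / 10)

  # tone present only in the manipulation window dominates the topography
  m <- line_montage(2)
  cfg <- sim_config(n_channels = 2, srate = 500, noise_sd_uv = 5,
    target_channels = "ch1", coil_channel = "ch1", seed = 11)
  proto <- build_protocol(1, 3, 0, seed = 11)
  prof <- list(subject = "S01", group = "sham", base_dprime_manip = 1,
    base_dprime_simple = 1, slope = 0, slope_simple = 0,
    theta_gain_uv = 6, entrain_gain_uv = 0, seed = 12L)
  epw <- simulate_epochs(prof, proto, NULL, m, cfg)
  envw <- band_envelope(epw) # z-scored
  bidx <- time_index_test(envw$times, c(-1000, 0))
  expect_gt(envw$topography[["ch1"]],
    mean(envw$envelope[1, bidx]) + 3)
})

test_that("Hilbert theta topography and Morlet 4-8 Hz topography agree in
           rank order across channels", {
  m <- line_montage(6, spacing = 40)
  cfg <- sim_config(n_channels = 6, srate = 500, noise_sd_uv = 5,
    target_channels = c("ch1", "ch2"), coil_channel = "ch1", seed = 13)
  proto <- build_protocol(1, 3, 0, seed = 13)
  prof <- list(subject = "S01", group = "sham", base_dprime_manip = 1,
    base_dprime_simple = 1, slope = 0, slope_simple = 0,
    theta_gain_uv = 8, entrain_gain_uv = 0, seed = 14L)
  ep <- simulate_epochs(prof, proto, NULL, m, cfg)
  env <- band_envelope(ep)
  tfr <- zscore_baseline(morlet_tfr(ep, freqs = 4:8, decim = 5))
  widx <- time_index_test(tfr$times, c(5000, 10000))
  topo_tfr <- apply(tfr$power[, , widx], 1, mean)
  rho <- stats::cor(env$topography, topo_tfr, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("tf_behavior_correlation: perfect, degenerate, and null cases", {
  # behavior exactly linear in one bin's power -> r = 1 there
  set.seed(15)
  maps <- lapply(1:6, function(i) {
    m <- matrix(stats::rnorm(4 * 5), 4, 5)
    m[2, 3] <- i * 0.5 + 1
    m
  })
  beh <- vapply(maps, function(m) 2 * m[2, 3] - 1, 0)
  cm <- tf_behavior_correlation(maps, beh)
  expect_equal(cm$r[2, 3], 1)
  expect_equal(dim(cm$r), c(4, 5))
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))

  # n = 3 subjects with maps collinear in behavior -> |r| = 1 everywhere
  beh3 <- c(1, 2, 5)
  slopes <- matrix(c(2, -1, 0.5, 3), 2, 2)
  maps3 <- lapply(beh3, function(b) slopes * b + 1)
  cm3 <- tf_behavior_correlation(maps3, beh3)
  expect_true(all(abs(cm3$r) > 1 - 1e-8))

  expect_error(tf_behavior_correlation(maps[1:2], beh[1:2]), ">= 3")
  expect_error(tf_behavior_correlation(maps, rep(1, 6)), "zero variance")

  # null: permuted behavior -> r distribution matches the t-based quantile
  n <- 10
  nulls <- replicate(400, {
    mm <- lapply(seq_len(n), function(i) stats::rnorm(3))
    tf_behavior_correlation(mm, stats::rnorm(n))$r[1]
  })
  expect_lt(abs(mean(nulls)), 0.05)
  tq <- stats::qt(0.975, n - 2)
  r95 <- tq / sqrt(tq^2 + n - 2) # r quantile implied by t distribution
  expect_lt(abs(stats::quantile(abs(nulls), 0.95) - r95), 0.08)
})
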