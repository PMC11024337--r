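# Signal-detection measures, screening, slopes, exact tests, effect size,
# and power planning.

test_that("dprime: chance, probit arithmetic, and clamp rule", {
  s <- dprime(10, 10, 10, 10)
  expect_equal(s$dprime, 0)
  expect_equal(s$c, 0)

  # H = 0.9, FA = 0.1 -> d' = 2 * qnorm(0.9) = 2.5631
  s2 <- dprime(18, 2, 2, 18)
  expect_equal(s2$dprime, 2 * stats::qnorm(0.9))
  expect_equal(round(s2$dprime, 4), 2.5631)

  # 42/42 hits clamps H to 1 - 1/84
  s3 <- dprime(42, 0, 10, 32)
  expect_equal(s3$H, 1 - 1 / 84)
  expect_equal(round(s3$H, 5), 0.98810)
  expect_true(s3$correction_applied)

  # antisymmetry under swapping signal/noise labels
  s4 <- dprime(15, 5, 8, 12)
  s4swap <- dprime(8, 12, 15, 5)
  expect_equal(s4swap$dprime, -s4$dprime)

  expect_error(dprime(0, 0, 5, 5), "present")
})

test_that("hits_minus_fa and screening rules", {
  rows <- data.frame(
    is_match = rep(c(FALSE, TRUE), each = 10),
    response = c(rep("mismatch", 8), rep("match", 2),
      rep("mismatch", 2), rep("match", 8))
  )
  expect_equal(hits_minus_fa(rows), 0.6)
  perfect <- data.frame(is_match = c(FALSE, TRUE),
    response = c("mismatch", "match"))
  expect_equal(hits_minus_fa(perfect), 1.0) # no clamping here
  expect_error(hits_minus_fa(rows[rows$is_match, ]), "present")

  expect_equal(screen_subject(0.75), "exclude_ceiling")
  expect_equal(screen_subject(0.00), "exclude_low")
  expect_equal(screen_subject(0.40), "enroll")
  expect_equal(screen_subject(0.70), "enroll") # bound is strict
})

test_that("learning_slope is exact on lines and unbiased under noise", {
  expect_equal(learning_slope(rep(1, 5))$slope, 0)
  fit <- learning_slope(c(1.0, 1.2, 1.4, 1.6, 1.8))
  expect_equal(fit$slope, 0.2)
  expect_equal(fit$intercept, 0.6)
  expect_error(learning_slope(c(1), sessions = 2), "2 sessions")

  set.seed(30)
  slopes <- replicate(2000, {
    learning_slope(0.5 + 0.2 * (2:6) + stats::rnorm(5, 0, 0.3))$slope
  })
  expect_lt(abs(mean(slopes) - 0.2), 0.01)
})

test_that("Mann-Whitney U: conventions and exact agreement with the
           enumeration oracle", {
  r <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  # identical multisets: U at midpoint, p in the 1.0 region
  ri <- mannwhitney_u(c(1.2, 3.4, 5.6), c(1.2, 3.4, 5.6))
  expect_gte(ri$p, 0.9)

  set.seed(31)
  for (rep in 1:25) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- stats::rnorm(nx)
    y <- stats::rnorm(ny, 0.5)
    for (tl in c("two", "greater", "less")) {
      expect_equal(mannwhitney_u(x, y, tl)$p, oracle_mw_p(x, y, tl),
        tolerance = 1e-12, info = sprintf("n=(%d,%d) tail=%s", nx, ny, tl))
    }
  }

  # exact vs normal approximation agree within 0.02 at n = 7 vs 7
  set.seed(32)
  for (rep in 1:10) {
    x <- stats::rnorm(7)
    y <- stats::rnorm(7, 0.8)
    pe <- mannwhitney_u(x, y)$p
    # force the normal path by adding a tie pair beyond n threshold
    xx <- c(x, 100, 101, 102, 103)
    yy <- c(y, 100, 101, 102, 103)
    pn <- mannwhitney_u(xx, yy)$p
    expect_equal(mannwhitney_u(x, y)$method, "exact")
    expect_equal(mannwhitney_u(xx, yy)$method, "normal")
    # direct comparison on the same data, normal vs exact
    mu <- 7 * 7 / 2
    sig <- sqrt(7 * 7 * 15 / 12)
    u <- mannwhitney_u(x, y)$U
    p_norm <- min(1, 2 * stats::pnorm((u - mu + 0.5) / sig))
    expect_lt(abs(pe - p_norm), 0.02)
  }
  expect_error(mannwhitney_u(numeric(0), 1), "empty")
})

test_that("Wilcoxon signed-rank: exact values and oracle agreement", {
  # n = 7, all positive differences, one-tailed: W = 28, p = 1/128
  r <- wilcoxon_signed(c(0.5, 1, 1.5, 2, 2.5, 3, 3.5), tail = "greater")
  expect_equal(r$W, 28)
  expect_equal(r$p, 1 / 128)

  # n = 7, W = 26 (smallest two ranks negative... rank 2 negative)
  d <- c(-0.2, 0.5, 1, 1.5, 2, 2.5, 3) # |d| ranks: 1..7, rank 1 negative
  r2 <- wilcoxon_signed(d, tail = "greater")
  expect_equal(r2$W, 27)
  d3 <- c(0.2, -0.5, 1, 1.5, 2, 2.5, 3) # rank 2 negative -> W = 26
  r3 <- wilcoxon_signed(d3, tail = "greater")
  expect_equal(r3$W, 26)
  expect_equal(r3$p, 3 / 128)

  # antisymmetric differences: two-tailed p in the 1.0 region
  ra <- wilcoxon_signed(c(-2, -1, 1, 2) + c(-1e-9, 0, 0, 1e-9))
  expect_gte(ra$p, 0.85)

  # zeros dropped and logged
  rz <- wilcoxon_signed(c(0, 0, 1, 2, -0.5))
  expect_equal(rz$n_zero, 2)
  expect_equal(rz$n, 3)
  expect_error(wilcoxon_signed(c(0, 0)), "zero")

  set.seed(33)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    d <- stats::rnorm(n, 0.4)
    for (tl in c("two", "greater", "less")) {
      expect_equal(wilcoxon_signed(d, tail = tl)$p,
        oracle_wilcoxon_p(d, tl), tolerance = 1e-12,
        info = sprintf("n=%d tail=%s", n, tl))
    }
  }
})

test_that("Cohen's d and sample-size planning", {
  expect_equal(round(cohens_d(2.4, 0.9, 1.4, 1.1), 3), 0.995)
  expect_equal(cohens_d(1, 1, 1, 2), 0)
  expect_equal(cohens_d(1, 1, 0, 1), 1)
  expect_error(cohens_d(1, 0, 0, 0), "pooled")

  ss <- required_sample_size(0.995)
  expect_equal(ss$n_per_group, 17)
  expect_equal(ss$total, 34)
  expect_gte(ss$achieved_power, 0.8)
  # power just below at n - 1
  expect_lt(ttest_power(16, 0.995), 0.8)
  # monotonicity
  expect_gt(required_sample_size(0.5)$n_per_group,
    required_sample_size(1.0)$n_per_group)
  expect_equal(required_sample_size(1.0)$n_per_group, 17)
})

test_that("unbiased percent correct matches the closed form", {
  expect_equal(unbiased_percent_correct(0), 50)
  expect_equal(round(unbiased_percent_correct(0.5), 2), 59.87)
  expect_equal(round(unbiased_percent_correct(2.5), 2), 89.44)
  expect_error(unbiased_percent_correct(-1), ">= 0")
})

test_that("dprime_table and slope_table aggregate behavior tables", {
  proto <- build_protocol(1, 40, 20, seed = 34)
  co <- simulate_cohort(2, seed = 35)
  beh <- do.call(rbind, lapply(1:4, function(i) {
    do.call(rbind, lapply(2:6, function(s) {
      simulate_responses(co[i, ], proto, s)
    }))
  }))
  dp <- dprime_table(beh)
  expect_equal(nrow(dp), 4 * 5)
  expect_true(all(is.finite(dp$dprime)))
  sl <- slope_table(dp)
  expect_equal(nrow(sl), 4)
  expect_setequal(sl$subject, unique(beh$subject))
})
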