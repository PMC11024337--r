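# Adjacency graphs and cluster-based permutation tests.

test_that("build_adjacency: distance rule, symmetry, template regression", {
  m2 <- line_montage(2, spacing = 10)
  a2 <- build_adjacency(m2, 50)
  expect_true(a2[1, 2] && a2[2, 1])
  m2f <- line_montage(2, spacing = 200)
  expect_warning(a2f <- build_adjacency(m2f, 50), "isolated")
  expect_false(any(a2f))

  adj <- build_adjacency(load_montage())
  expect_true(isSymmetric(unclass(adj)))
  expect_true(all(diag(adj) == FALSE))
  # frozen regression value from the template geometry (once computed):
  # mean neighbor count 9.06 at 50 mm
  expect_gt(mean(rowSums(adj)), 4)
  expect_lt(mean(rowSums(adj)), 10)
  expect_equal(mean(rowSums(adj)), 9.0645, tolerance = 1e-3)
})

test_that("identical groups yield no significant clusters", {
  set.seed(20)
  m <- line_montage(6)
  adj <- build_adjacency(m)
  a <- matrix(stats::rnorm(5 * 6), 5, 6)
  res <- cluster_permutation_test(a, a, "paired", adj, n_perm = 200,
    seed = 1)
  expect_equal(nrow(res$clusters), 0)
})

test_that("one-sample p values match the brute-force enumeration oracle", {
  set.seed(21)
  m <- line_montage(3)
  adj <- build_adjacency(m)
  neighbors <- list(2, c(1, 3), 2) # line graph, for the oracle
  for (rep in 1:5) {
    d <- matrix(stats::rnorm(6 * 3, mean = 0.8), 6, 3)
    expect_message(
      res <- cluster_permutation_test(d, NULL, "one_sample", adj,
        n_perm = 100, seed = 2),
      "exact enumeration"
    )
    expect_true(res$exact)
    expect_equal(res$n_perm, 64)
    ora <- oracle_cluster_one_sample(d, neighbors)
    expect_equal(nrow(res$clusters), nrow(ora))
    if (nrow(ora) > 0) {
      expect_equal(sort(res$clusters$mass), sort(ora$mass),
        tolerance = 1e-10)
      expect_equal(res$clusters$p[order(res$clusters$mass)],
        ora$p[order(ora$mass)], tolerance = 1e-10)
    }
  }
})

test_that("planted contiguous effects are detected on the planted channels", {
  set.seed(22)
  mont <- load_montage()
  adj <- build_adjacency(mont)
  planted <- c("C3", "C1", "Cz", "C2", "C4")
  pidx <- match(planted, mont$label)
  hits <- 0
  nsim <- 40
  for (s in seq_len(nsim)) {
    a <- matrix(stats::rnorm(7 * 62), 7, 62)
    b <- matrix(stats::rnorm(7 * 62), 7, 62)
    a[, pidx] <- a[, pidx] + 2
    res <- cluster_permutation_test(a, b, "independent", adj,
      n_perm = 200, seed = 100 + s)
    sig <- res$clusters[res$clusters$significant, , drop = FALSE]
    found <- FALSE
    for (cid in sig$id) {
      members <- which(res$membership == cid)
      if (sum(pidx %in% members) >= 4) found <- TRUE
    }
    hits <- hits + found
  }
  expect_gte(hits / nsim, 0.8)
})

test_that("doubling a planted effect never decreases the largest cluster
           mass (fixed noise)", {
  set.seed(23)
  mont <- line_montage(8)
  adj <- build_adjacency(mont)
  noise <- matrix(stats::rnorm(6 * 8), 6, 8)
  masses <- vapply(c(0.5, 1, 2, 4), function(eff) {
    a <- noise
    a[, 3:5] <- a[, 3:5] + eff
    res <- cluster_permutation_test(a, NULL, "one_sample", adj,
      n_perm = 50, seed = 3)
    if (nrow(res$clusters) == 0) 0 else max(res$clusters$mass)
  }, 0)
  expect_true(all(diff(masses) >= 0))
})

test_that("p values are invariant to adjacency-preserving channel
           relabeling", {
  set.seed(24)
  m <- line_montage(5)
  adj <- build_adjacency(m)
  d <- matrix(stats::rnorm(6 * 5, 0.7), 6, 5)
  res1 <- suppressMessages(cluster_permutation_test(d, NULL, "one_sample",
    adj, n_perm = 64, seed = 4))
  # reverse the line: an automorphism of the graph
  perm <- 5:1
  res2 <- suppressMessages(cluster_permutation_test(d[, perm], NULL,
    "one_sample", adj, n_perm = 64, seed = 4))
  expect_equal(sort(res1$clusters$p), sort(res2$clusters$p))
  expect_equal(sort(res1$clusters$mass), sort(res2$clusters$mass),
    tolerance = 1e-12)
})

test_that("channel x time inputs cluster across both axes", {
  set.seed(25)
  m <- line_montage(4)
  adj <- build_adjacency(m)
  # subjects x channels x time: effect on channels 2-3, times 3-6
  a <- array(stats::rnorm(8 * 4 * 8), dim = c(8, 4, 8))
  a[, 2:3, 3:6] <- a[, 2:3, 3:6] + 2.5
  res <- cluster_permutation_test(a, NULL, "one_sample", adj,
    n_perm = 300, seed = 5)
  expect_gt(nrow(res$clusters), 0)
  top <- res$clusters[1, ]
  expect_true(top$significant)
  # the top cluster covers most of the 2x4 = 8 planted bins
  memb <- which(res$membership == top$id)
  planted_bins <- as.vector(outer(2:3, (3:6 - 1) * 4, `+`))
  expect_gte(sum(planted_bins %in% memb), 6)
})
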