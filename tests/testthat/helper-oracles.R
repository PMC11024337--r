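# Independent oracles and small fixtures used across the suite. These stay
# deliberately naive (periodogram sums, brute-force enumeration) so they
# cannot share a code path with the implementation they check.

# band power by raw periodogram over a window (Welch-style oracle)
oracle_band_power <- function(x, srate, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * srate
  sum(sp[f >= lo & f <= hi])
}

# exact Mann-Whitney p by enumerating all C(nx+ny, nx) group assignments
oracle_mw_p <- function(x, y, tail = "two") {
  nx <- length(x)
  ny <- length(y)
  all_v <- c(x, y)
  u_of <- function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  ux_obs <- u_of(seq_len(nx))
  uy_obs <- nx * ny - ux_obs
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, u_of)
  switch(tail,
    # symmetric null: two-sided p doubles P(U_x <= u_min)
    two = min(1, 2 * mean(u_all <= min(ux_obs, uy_obs))),
    greater = mean((nx * ny - u_all) <= uy_obs),
    less = mean(u_all <= ux_obs)
  )
}

# exact Wilcoxon signed-rank p by enumerating all 2^n sign patterns
oracle_wilcoxon_p <- function(d, tail = "two") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  switch(tail,
    greater = mean(w_all >= w_obs),
    less = mean(w_all <= w_obs),
    two = min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  )
}

# brute-force one-sample cluster permutation p values on a tiny graph:
# enumerate all sign flips, t per bin, threshold, clusters by neighbor
# list, max-mass null. Returns data.frame of observed clusters with p.
oracle_cluster_one_sample <- function(d, neighbors, cluster_alpha = 0.05,
                                      tail = 1) {
  n <- nrow(d)
  tcrit <- stats::qt(1 - cluster_alpha, n - 1)
  tstat <- function(mat) {
    apply(mat, 2, function(v) mean(v) / (stats::sd(v) / sqrt(length(v))))
  }
  clusters_of <- function(tv) {
    supra <- if (tail >= 0) tv > tcrit else tv < -tcrit
    seen <- rep(FALSE, length(tv))
    out <- list()
    for (s in which(supra)) {
      if (seen[s]) next
      comp <- s
      seen[s] <- TRUE
      repeat {
        grow <- unique(unlist(neighbors[comp]))
        grow <- grow[supra[grow] & !seen[grow]]
        if (length(grow) == 0) break
        seen[grow] <- TRUE
        comp <- c(comp, grow)
      }
      out[[length(out) + 1]] <- comp
    }
    out
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(signs, 1, function(s) {
    tv <- tstat(d * s)
    cl <- clusters_of(tv)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, function(m) sum(tv[m]), 0)))
  })
  tv <- tstat(d)
  cl <- clusters_of(tv)
  if (length(cl) == 0) {
    return(data.frame(mass = numeric(0), p = numeric(0)))
  }
  data.frame(
    mass = vapply(cl, function(m) sum(tv[m]), 0),
    p = vapply(cl, function(m) {
      mean(null_max >= abs(sum(tv[m])))
    }, 0)
  )
}

# half-open window index on a time axis (mirrors the package convention)
time_index_test <- function(times, w) which(times >= w[1] & times < w[2])

# tiny line-graph montage: k channels 30 mm apart along x
line_montage <- function(k, spacing = 30) {
  as_m <- data.frame(
    label = paste0("ch", seq_len(k)),
    x = (seq_len(k) - 1) * spacing, y = 0, z = 0
  )
  class(as_m) <- c("montage", "data.frame")
  as_m
}

# small epochs object with known content
toy_epochs <- function(ntr = 2, nch = 3, n = 1000, srate = 500,
                       fill = function(i, ch, tt) numeric(length(tt))) {
  times <- seq(-200, by = 1000 / srate, length.out = n)
  arr <- array(0, dim = c(ntr, nch, n))
  for (i in seq_len(ntr)) {
    for (ch in seq_len(nch)) {
      arr[i, ch, ] <- fill(i, ch, times / 1000)
    }
  }
  eeg_epochs(arr, srate, times, paste0("ch", seq_len(nch)))
}
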