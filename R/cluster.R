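# Sensor-space cluster-based permutation tests (Maris-Oostenveld scheme):
# point-wise t statistics, supra-threshold bins grouped into spatially
# contiguous clusters, cluster mass = sum of member t values, and a
# max-cluster-mass permutation null (sign flips or group-label shuffles).

#' Build a channel adjacency graph from a montage
#'
#' Channels are neighbors iff their Euclidean distance is at most
#' `max_dist_mm`. Isolated channels trigger a warning but are allowed.
#'
#' @param montage a [load_montage()] result.
#' @param max_dist_mm neighbor threshold in mm (default 50).
#' @return an `adjacency` object: logical channels x channels matrix
#'   (symmetric, zero diagonal) with attribute `max_dist_mm`.
#' @export
build_adjacency <- function(montage, max_dist_mm = 50) {
  stopifnot(nrow(montage) >= 2)
  pos <- as.matrix(montage[c("x", "y", "z")])
  dm <- as.matrix(stats::dist(pos))
  adj <- dm <= max_dist_mm
  diag(adj) <- FALSE
  dimnames(adj) <- list(montage$label, montage$label)
  iso <- rowSums(adj) == 0
  if (any(iso)) {
    warning("build_adjacency: isolated channels: ",
      paste(montage$label[iso], collapse = ", "))
  }
  structure(adj, max_dist_mm = max_dist_mm, class = c("adjacency", "matrix"))
}

# neighbor list for bins laid out as channels x extra grid dims.
# Contiguity = channel adjacency at the same grid cell, or |delta| <= 1
# along exactly one ordered axis at the same channel... combined per the
# FieldTrip convention: bins (c1, g1) and (c2, g2) are neighbors iff
# (g1 == g2 and adjacent(c1, c2)) or (c1 == c2 and g differs by 1 in one
# axis).
bin_neighbors <- function(adj, grid_dims = NULL) {
  nch <- nrow(adj)
  adj_list <- lapply(seq_len(nch), function(i) which(adj[i, ]))
  if (is.null(grid_dims) || prod(grid_dims) == 1) {
    return(adj_list)
  }
  ng <- prod(grid_dims)
  nb <- vector("list", nch * ng)
  gidx <- arrayInd(seq_len(ng), .dim = grid_dims)
  # neighbors within the grid (|delta| = 1 along one axis)
  gnb <- lapply(seq_len(ng), function(g) {
    out <- integer(0)
    for (ax in seq_along(grid_dims)) {
      for (s in c(-1L, 1L)) {
        cell <- gidx[g, ]
        cell[ax] <- cell[ax] + s
        if (cell[ax] >= 1 && cell[ax] <= grid_dims[ax]) {
          out <- c(out, sum((cell - 1) * cumprod(c(1, grid_dims))[seq_along(cell)]) + 1L)
        }
      }
    }
    out
  })
  for (g in seq_len(ng)) {
    base <- (g - 1L) * nch
    for (ch in seq_len(nch)) {
      nb[[base + ch]] <- c(
        base + adj_list[[ch]],
        (gnb[[g]] - 1L) * nch + ch
      )
    }
  }
  nb
}

# connected components over supra-threshold bins; returns cluster id per bin
find_clusters <- function(supra, neighbors) {
  id <- integer(length(supra))
  cur <- 0L
  for (s in which(supra)) {
    if (id[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    id[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in neighbors[[v]]) {
        if (supra[w] && id[w] == 0L) {
          id[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  id
}

# max cluster mass for one t-map (vector over bins), given threshold/tail
max_cluster_mass <- function(tvec, tcrit, tail, neighbors) {
  supra <- if (tail >= 0) tvec > tcrit else tvec < -tcrit
  if (!any(supra)) return(0)
  id <- find_clusters(supra, neighbors)
  masses <- vapply(seq_len(max(id)), function(k) sum(tvec[id == k]), 0)
  max(abs(masses))
}

# t statistics for all permutations at once.
# one_sample: d = subjects x bins, S = n_perm x subjects sign matrix.
t_one_sample_perms <- function(d, S) {
  n <- nrow(d)
  ssq <- colSums(d^2) # invariant under sign flips
  m <- (S %*% d) / n
  v <- (rep(1, nrow(S)) %o% ssq - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

# independent: x = all subjects x bins, G = n_perm x n 0/1 matrix (group 1)
t_independent_perms <- function(x, G) {
  n1 <- sum(G[1, ])
  n <- nrow(x)
  n2 <- n - n1
  s <- colSums(x)
  ssq <- colSums(x^2)
  s1 <- G %*% x
  q1 <- G %*% x^2
  m1 <- s1 / n1
  m2 <- (rep(1, nrow(G)) %o% s - s1) / n2
  v1 <- q1 - n1 * m1^2
  v2 <- (rep(1, nrow(G)) %o% ssq - q1) - n2 * m2^2
  sp <- (v1 + v2) / (n1 + n2 - 2)
  sp[sp < .Machine$double.eps] <- .Machine$double.eps
  (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
}

#' Cluster-based permutation test
#'
#' One-sample, paired, or independent-samples test over channel
#' topographies (subjects x channels matrices) or channel x grid bins
#' (subjects x channels x ... arrays; contiguity along extra axes is
#' |delta| <= 1). Point-wise t values beyond the cluster-forming threshold
#' (the one-tailed t quantile at `cluster_alpha` with the design's df) are
#' grouped into connected clusters; the cluster statistic is the mass (sum
#' of t); the null is the permutation distribution of the maximum cluster
#' mass, with sign flips (one-sample/paired) or group-label shuffles
#' (independent). If the number of distinct permutations is at most
#' `n_perm`, exact enumeration is used instead and noted in the result.
#'
#' Cluster p values use the (1 + exceedances)/(1 + n_perm) correction (for
#' exact enumeration the identity permutation plays the +1 role), so p is
#' never 0. A cluster is significant iff p <= alpha.
#'
#' @param a subjects x bins data (matrix or array) for the first condition
#'   or group; for `one_sample`, difference-from-zero maps.
#' @param b second condition/group (paired or independent), or NULL.
#' @param design "one_sample", "paired", or "independent".
#' @param adjacency a [build_adjacency()] result.
#' @param alpha cluster significance level (default 0.05).
#' @param tail +1 (default, positive), -1, or 0 (two-sided).
#' @param cluster_alpha cluster-forming threshold quantile (default 0.05).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @return a `cluster_result`: list with `clusters` (data.frame: id, k,
#'   mass, p, significant; ascending p), `membership` (cluster id per bin,
#'   0 = none), `t` (observed t map), `tcrit`, `df`, `n_perm`, `exact`,
#'   `tail`, `design`, `seed`.
#' @export
cluster_permutation_test <- function(a, b = NULL,
                                     design = c("one_sample", "paired",
                                       "independent"),
                                     adjacency, alpha = 0.05, tail = 1,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = NULL) {
  design <- match.arg(design)
  dims_a <- if (is.null(dim(a))) c(length(a), 1) else dim(a)
  flatten <- function(x) {
    if (is.null(dim(x)) || length(dim(x)) == 2) {
      as.matrix(x)
    } else {
      matrix(x, dim(x)[1], prod(dim(x)[-1]))
    }
  }
  grid_dims <- if (length(dims_a) > 2) dims_a[-(1:2)] else NULL
  nch <- dims_a[2]
  stopifnot(nch == nrow(adjacency))
  neighbors <- bin_neighbors(unclass(adjacency), grid_dims)

  if (design == "paired") {
    stopifnot(!is.null(b), identical(dim(a), dim(b)))
    d <- flatten(a) - flatten(b)
    design_core <- "one_sample"
  } else if (design == "one_sample") {
    d <- flatten(a)
    design_core <- "one_sample"
  } else {
    stopifnot(!is.null(b))
    x <- rbind(flatten(a), flatten(b))
    n1 <- dims_a[1]
    design_core <- "independent"
  }

  if (design_core == "one_sample") {
    n <- nrow(d)
    stopifnot(n >= 2)
    df <- n - 1
    n_exact <- 2^n
    exact <- n_exact <= n_perm
    S_obs <- matrix(1, 1, n)
    S <- if (exact) {
      message("cluster_permutation_test: exact enumeration of ", n_exact,
        " sign flips")
      as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      with_seed(seed,
        matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
    }
    t_obs <- t_one_sample_perms(d, S_obs)[1, ]
    t_null <- t_one_sample_perms(d, S)
  } else {
    n <- nrow(x)
    n2 <- n - n1
    stopifnot(n1 >= 2, n2 >= 2)
    df <- n - 2
    n_exact <- choose(n, n1)
    exact <- n_exact <= n_perm
    G_obs <- matrix(0, 1, n)
    G_obs[1, seq_len(n1)] <- 1
    G <- if (exact) {
      message("cluster_permutation_test: exact enumeration of ", n_exact,
        " group assignments")
      combs <- utils::combn(n, n1)
      t(apply(combs, 2, function(idx) {
        g <- numeric(n)
        g[idx] <- 1
        g
      }))
    } else {
      with_seed(seed, t(vapply(seq_len(n_perm), function(i) {
        g <- numeric(n)
        g[sample.int(n, n1)] <- 1
        g
      }, numeric(n))))
    }
    t_obs <- t_independent_perms(x, G_obs)[1, ]
    t_null <- t_independent_perms(x, G)
  }

  tcrit <- if (tail == 0) {
    stats::qt(1 - cluster_alpha / 2, df)
  } else {
    stats::qt(1 - cluster_alpha, df)
  }

  null_max <- vapply(seq_len(nrow(t_null)), function(i) {
    if (tail == 0) {
      max(
        max_cluster_mass(t_null[i, ], tcrit, 1, neighbors),
        max_cluster_mass(t_null[i, ], tcrit, -1, neighbors)
      )
    } else {
      max_cluster_mass(t_null[i, ], tcrit, tail, neighbors)
    }
  }, 0)

  obs_clusters <- function(tv, tl) {
    supra <- if (tl >= 0) tv > tcrit else tv < -tcrit
    if (!any(supra)) {
      return(list(id = integer(length(tv)), df = NULL))
    }
    id <- find_clusters(supra, neighbors)
    cl <- data.frame(
      id = seq_len(max(id)),
      k = as.integer(tabulate(id[id > 0], max(id))),
      mass = vapply(seq_len(max(id)), function(kk) sum(tv[id == kk]), 0)
    )
    list(id = id, df = cl)
  }

  if (tail == 0) {
    pos <- obs_clusters(t_obs, 1)
    neg <- obs_clusters(t_obs, -1)
    membership <- pos$id
    if (!is.null(neg$df)) {
      offs <- if (is.null(pos$df)) 0L else max(pos$df$id)
      neg$df$id <- neg$df$id + offs
      membership[neg$id > 0] <- neg$id[neg$id > 0] + offs
    }
    clusters <- rbind(pos$df, neg$df)
  } else {
    res <- obs_clusters(t_obs, tail)
    membership <- res$id
    clusters <- res$df
  }

  denom <- if (exact) nrow(t_null) else nrow(t_null) + 1
  if (is.null(clusters)) {
    clusters <- data.frame(id = integer(0), k = integer(0),
      mass = numeric(0), p = numeric(0), significant = logical(0))
  } else {
    clusters$p <- vapply(clusters$mass, function(m) {
      exc <- sum(null_max >= abs(m))
      if (exact) exc / denom else (1 + exc) / denom
    }, 0)
    clusters$significant <- clusters$p <= alpha
    ord <- order(clusters$p, -abs(clusters$mass))
    clusters <- clusters[ord, , drop = FALSE]
    rownames(clusters) <- NULL
  }

  structure(
    list(
      clusters = clusters, membership = membership, t = t_obs,
      tcrit = tcrit, df = df, n_perm = nrow(t_null), exact = exact,
      tail = tail, design = design, alpha = alpha,
      cluster_alpha = cluster_alpha, seed = seed,
      null_max = null_max
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %s, tail %+d, %d bins, %s%d permutations\n",
    x$design, x$tail, length(x$t), if (x$exact) "exact " else "", x$n_perm
  ))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(utils::head(x$clusters, 5))
  }
  invisible(x)
}
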