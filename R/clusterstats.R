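#' Baseline-corrected motion index
#'
#' `MI = (MR_InPhase - MR_ShamIn) - (MR_AntiPhase - MR_ShamAnti)`: the
#' sham-corrected difference of the motion ratio between the in-phase and
#' anti-phase sessions; one value per subject. Antisymmetric under swapping
#' the in-/anti-phase arguments.
#'
#' @param mr_in,mr_sham_in,mr_anti,mr_sham_anti motion ratios in \[0, 1\]
#'   (vectorized over subjects).
#' @return numeric MI.
#' @export
motion_index <- function(mr_in, mr_sham_in, mr_anti, mr_sham_anti) {
  vals <- c(mr_in, mr_sham_in, mr_anti, mr_sham_anti)
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) stop("motion ratios must lie in [0, 1]")
  (mr_in - mr_sham_in) - (mr_anti - mr_sham_anti)
}

#' Student transform of a correlation coefficient
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n` the number of subjects.
#'
#' @param r correlation coefficient, `|r| < 1`.
#' @param n number of subjects (>= 3).
#' @return t-value (odd in r).
#' @export
r_to_t <- function(r, n) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  if (n < 3) stop("need n >= 3")
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

# connected components of the supra-threshold subgraph; returns list of
# integer member vectors
components_of <- function(supra, adjacency) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  comp <- list()
  visited <- logical(length(supra))
  for (s in idx) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; members <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adjacency[v, ] & supra & !visited)
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
        members <- c(members, nb)
      }
    }
    comp[[length(comp) + 1L]] <- sort(members)
  }
  comp
}

# max over sign-separated clusters of |sum t|; 0 when nothing supra-threshold
max_cluster_stat <- function(t, thresh, adjacency, min_cluster = 1L) {
  best <- 0
  for (sgn in c(1, -1)) {
    supra <- (sgn * t) > thresh
    for (m in components_of(supra, adjacency)) {
      if (length(m) < min_cluster) next
      best <- max(best, abs(sum(t[m])))
    }
  }
  best
}

new_cluster_result <- function(clusters, n_perm, cluster_alpha, seed, kind,
                               null_dist) {
  structure(
    list(clusters = clusters, n_permutations = n_perm,
         cluster_alpha = cluster_alpha, seed = seed, kind = kind,
         null_quantile95 = stats::quantile(null_dist, 0.95, names = FALSE)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", x$kind, ": ", nrow(x$clusters), " cluster(s), ",
      x$n_permutations, " permutations (cluster alpha ", x$cluster_alpha,
      ")\n", sep = "")
  if (nrow(x$clusters)) {
    print(tibble::as_tibble(x$clusters[c("cluster", "size", "sum_t", "p.value",
                                         "significant")]))
  }
  invisible(x)
}

#' Cluster-based permutation test (dependent-samples t)
#'
#' Element-wise paired t-tests between two conditions over subjects;
#' supra-threshold elements (two-sided, element alpha = `cluster_alpha`) are
#' clustered by adjacency, separately for positive and negative t, and each
#' cluster's summed t is compared with the permutation null obtained by
#' randomly switching condition labels within subjects (sign flips of the
#' paired differences), taking the maximal |cluster sum| per iteration. A
#' cluster is significant when its statistic exceeds the 95th percentile of
#' the null. Elements with degenerate variance are excluded.
#'
#' @param x,y subject x element matrices (paired conditions).
#' @param adjacency element adjacency (logical matrix). For sensor-by-
#'   frequency grids build it with [grid_adjacency()].
#' @param cluster_alpha element-level threshold alpha (default 0.05).
#' @param n_perm permutations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return a `cluster_result`; `tidy()` gives the cluster table.
#' @export
cluster_perm_ttest <- function(x, y, adjacency, cluster_alpha = 0.05,
                               n_perm = 1000, seed = 1) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  n <- nrow(x); ne <- ncol(x)
  if (n < 2) stop("need at least 2 subjects")
  stopifnot(nrow(adjacency) == ne, ncol(adjacency) == ne)
  if (n_perm < 100) warning("fewer than 100 permutations is unreliable")
  D <- x - y
  sds <- apply(D, 2, stats::sd)
  ok <- sds > 0
  tobs <- rep(0, ne)
  tobs[ok] <- colMeans(D[, ok, drop = FALSE]) / (sds[ok] / sqrt(n))
  thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- (S %*% D) / n                      # per-perm means
  q <- colSums(D^2) / n                   # invariant second moment
  Vp <- sweep(-M^2, 2, q, "+") * n / (n - 1)
  Tp <- M / sqrt(pmax(Vp, .Machine$double.eps) / n)
  Tp[, !ok] <- 0

  null <- vapply(seq_len(n_perm), function(i) {
    max_cluster_stat(Tp[i, ], thresh, adjacency)
  }, numeric(1))

  clusters <- collect_clusters(tobs, thresh, adjacency, null, n_perm,
                               min_cluster = 1L, sig_alpha = 0.05)
  new_cluster_result(clusters, n_perm, cluster_alpha, seed,
                     "dependent-t", null)
}

collect_clusters <- function(tobs, thresh, adjacency, null, n_perm,
                             min_cluster, sig_alpha) {
  rows <- list()
  for (sgn in c(1, -1)) {
    for (m in components_of((sgn * tobs) > thresh, adjacency)) {
      if (length(m) < min_cluster) next
      s <- sum(tobs[m])
      p <- (1 + sum(null >= abs(s))) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        members = list(m), size = length(m), sum_t = s, p.value = p)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(cluster = integer(), members = list(),
                          size = integer(), sum_t = numeric(),
                          p.value = numeric(), significant = logical()))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$p.value, -abs(out$sum_t)), ]
  out$cluster <- seq_len(nrow(out))
  out$significant <- out$p.value < sig_alpha
  out[c("cluster", "members", "size", "sum_t", "p.value", "significant")]
}

#' Cluster-based permuted correlation test
#'
#' Per element (channel pair), the Pearson correlation across subjects
#' between a per-subject scalar (e.g. the motion index) and a per-subject
#' map (e.g. the in-phase minus anti-phase coherence difference) is
#' transformed to t with [r_to_t()]. Elements with two-sided p below
#' `cluster_alpha` (default 20%) are clustered by adjacency; the null
#' switches condition labels within subjects (sign-flipping the difference
#' maps while the scalar stays fixed; `scheme = "shuffle_mi"` instead
#' permutes the scalar across subjects), recording the largest |cluster
#' sum t| per iteration. Only clusters spanning at least `min_cluster`
#' adjacent elements with permutation p < 0.05 are flagged significant.
#'
#' @param delta subject x element matrix of condition differences.
#' @param mi numeric vector, one scalar per subject.
#' @param adjacency element adjacency (logical matrix).
#' @param cluster_alpha element-level threshold alpha (default 0.20).
#' @param n_perm permutations (default 1000).
#' @param min_cluster minimal cluster extent reported significant (default 2).
#' @param seed integer seed.
#' @param scheme permutation scheme (see above).
#' @return a `cluster_result`.
#' @export
cluster_perm_correlation <- function(delta, mi, adjacency,
                                     cluster_alpha = 0.20, n_perm = 1000,
                                     min_cluster = 2, seed = 1,
                                     scheme = c("sign_flip", "shuffle_mi")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(delta), length(mi) == nrow(delta))
  n <- nrow(delta); ne <- ncol(delta)
  if (n < 4) stop("need at least 4 subjects")
  stopifnot(nrow(adjacency) == ne, ncol(adjacency) == ne)
  if (n_perm < 100) warning("fewer than 100 permutations is unreliable")

  sds <- apply(delta, 2, stats::sd)
  ok <- sds > 0 & stats::sd(mi) > 0
  robs <- rep(0, ne)
  robs[ok] <- as.vector(stats::cor(mi, delta[, ok, drop = FALSE]))
  robs <- pmin(pmax(robs, -0.999999), 0.999999)
  tobs <- r_to_t(robs, n)
  thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 2)

  set.seed(seed)
  null <- numeric(n_perm)
  mi_c <- mi - mean(mi)
  if (scheme == "sign_flip") {
    # r under per-subject sign flip, vectorized: only the cross moment and
    # the mean of the flipped maps change; sum of squares is invariant
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    cross <- S * matrix(mi_c, n_perm, n, byrow = TRUE)
    num <- cross %*% delta                      # sum mi_c * s * d
    Msd <- (S %*% delta) / n                    # mean of flipped maps
    ssd <- colSums(delta^2)
    sd_mi <- sqrt(sum(mi_c^2) / (n - 1))
    for (i in seq_len(n_perm)) {
      vard <- (ssd - n * Msd[i, ]^2) / (n - 1)
      r <- num[i, ] / ((n - 1) * sqrt(pmax(vard, .Machine$double.eps)) * sd_mi)
      r[!ok] <- 0
      r <- pmin(pmax(r, -0.999999), 0.999999)
      null[i] <- max_cluster_stat(r_to_t(r, n), thresh, adjacency, min_cluster)
    }
  } else {
    for (i in seq_len(n_perm)) {
      r <- as.vector(stats::cor(mi[sample.int(n)], delta))
      r[!ok | !is.finite(r)] <- 0
      r <- pmin(pmax(r, -0.999999), 0.999999)
      null[i] <- max_cluster_stat(r_to_t(r, n), thresh, adjacency, min_cluster)
    }
  }

  clusters <- collect_clusters(tobs, thresh, adjacency, null, n_perm,
                               min_cluster = min_cluster, sig_alpha = 0.05)
  new_cluster_result(clusters, n_perm, cluster_alpha, seed,
                     "correlation", null)
}

#' Adjacency for a sensor-by-frequency grid
#'
#' Elements are laid out sensor-major (`sensor + (freq - 1) * n_sensors`).
#' Two elements are adjacent when they share the frequency and their sensors
#' are adjacent, or share the sensor and their frequencies are neighbors at
#' the grid resolution (1 Hz bins link across band boundaries).
#'
#' @param space_adj sensor (or sensor-pair) adjacency, logical matrix.
#' @param n_freq number of frequency bins.
#' @return logical matrix of size `(n_sensors * n_freq)^2`.
#' @export
grid_adjacency <- function(space_adj, n_freq) {
  ns <- nrow(space_adj)
  n <- ns * n_freq
  out <- matrix(FALSE, n, n)
  for (f in seq_len(n_freq)) {
    off <- (f - 1L) * ns
    out[off + seq_len(ns), off + seq_len(ns)] <- space_adj
    if (f < n_freq) {
      idx <- cbind(off + seq_len(ns), off + ns + seq_len(ns))
      out[idx] <- TRUE
      out[idx[, 2:1]] <- TRUE
    }
  }
  diag(out) <- FALSE
  out
}
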