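# Independent oracles and fixtures used across the test suite.

# Brute-force Victor-Purpura oracle: minimize over all equal-size sorted
# subset pairs (every monotone spike matching), cost = unmatched spikes + q
# times total shift. Exponential; only for trains with <= ~5 spikes.
vp_brute <- function(a, b, q) {
  na <- length(a); nb <- length(b)
  best <- na + nb  # delete everything
  for (k in seq_len(min(na, nb))) {
    ia <- utils::combn(na, k)
    ib <- utils::combn(nb, k)
    for (i in seq_len(ncol(ia))) {
      for (j in seq_len(ncol(ib))) {
        cost <- (na - k) + (nb - k) +
          q * sum(abs(a[ia[, i]] - b[ib[, j]]))
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# Independent reference DP in plain R (full table, no rolling rows).
vp_ref <- function(a, b, q) {
  na <- length(a); nb <- length(b)
  D <- matrix(0, na + 1L, nb + 1L)
  D[, 1L] <- 0:na
  D[1L, ] <- 0:nb
  for (i in seq_len(na))
    for (j in seq_len(nb))
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1, D[i + 1L, j] + 1,
                               D[i, j] + q * abs(a[i] - b[j]))
  D[na + 1L, nb + 1L]
}

random_train <- function(max_spikes, duration = 1) {
  sort(runif(sample.int(max_spikes + 1L, 1L) - 1L, 0, duration))
}

# Homogeneous-Poisson ensemble with no condition structure.
poisson_recording <- function(n_neurons, n_windows, rate = 10, duration = 1,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trains <- replicate(n_neurons, replicate(n_windows,
    sort(runif(rpois(1L, rate * duration), 0, duration)),
    simplify = FALSE), simplify = FALSE)
  ensemble_recording(trains, duration = duration)
}

# Well-separated Gaussian blobs in 2-D.
make_blobs <- function(centers, n_per = 30, sdev = 0.1, seed = 1) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(n_per, centers[i, 1], sdev), rnorm(n_per, centers[i, 2], sdev))))
  list(coords = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Residual error after optimally rotating/reflecting/translating Y onto X.
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(sum((Yc %*% R - Xc)^2))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
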