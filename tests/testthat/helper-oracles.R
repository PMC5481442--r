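# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# brute-force Layman metrics from explicit loops over pairwise distances
oracle_layman <- function(pts) {
  n <- nrow(pts)
  cx <- sum(pts[, 1]) / n
  cy <- sum(pts[, 2]) / n
  cd <- 0
  for (i in seq_len(n)) cd <- cd + sqrt((pts[i, 1] - cx)^2 + (pts[i, 2] - cy)^2)
  cd <- cd / n
  nnd <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2)
      if (d < best) best <- d
    }
    nnd[i] <- best
  }
  m <- sum(nnd) / n
  sdnnd <- sqrt(sum((nnd - m)^2) / (n - 1))
  c(NR = max(pts[, 2]) - min(pts[, 2]),
    CR = max(pts[, 1]) - min(pts[, 1]),
    CD = cd, NND = m, SDNND = sdnnd)
}

# closed-form intersection area of two circles with radius r, centres d apart
oracle_lens_area <- function(r, d) {
  if (d >= 2 * r) return(0)
  2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
}

# rescale a point cloud so its sample covariance is exactly `target`
# (empirical whitening followed by recolouring); the result has sample
# mean exactly zero so clouds can be placed at known centres
whiten_to <- function(pts, target = diag(2)) {
  pts <- as.matrix(pts)
  ctr <- scale(pts, center = TRUE, scale = FALSE)
  e <- eigen(stats::cov(ctr), symmetric = TRUE)
  w <- ctr %*% e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  et <- eigen(target, symmetric = TRUE)
  half <- et$vectors %*% diag(sqrt(et$values)) %*% t(et$vectors)
  w %*% half
}

# simplex-grid + importance-sampling posterior for the mixing model, written
# directly from the likelihood definition (no package internals). Returns
# marginal posterior means of the diet proportions.
# grid: all p on the K-simplex with step `step`; tau integrated by Monte
# Carlo over its half-normal prior (common draws across grid points).
oracle_mixing_posterior_mean <- function(x, sources, tef, step = 0.02,
                                         alpha = 1, tau_prior_sd = 5,
                                         n_tau = 200, seed = 99) {
  K <- nrow(sources)
  steps <- round(1 / step)
  grid <- if (K == 2) {
    a <- 0:steps
    cbind(a, steps - a)
  } else if (K == 3) {
    g <- NULL
    for (a in 0:steps) for (b in 0:(steps - a)) g <- rbind(g, c(a, b, steps - a - b))
    g
  } else {
    stop("oracle supports K = 2 or 3")
  }
  P <- grid / steps
  inner <- P > 0 & P < 1
  mu_src <- cbind(sources$mean_d13C + tef$mean_d13C,
                  sources$mean_d15N + tef$mean_d15N)
  s2_src <- cbind(sources$sd_d13C^2 + tef$sd_d13C^2,
                  sources$sd_d15N^2 + tef$sd_d15N^2)
  set.seed(seed)
  taus <- matrix(abs(rnorm(2 * n_tau, 0, tau_prior_sd)), n_tau, 2)
  n <- nrow(x)
  log_w <- matrix(0, nrow(P), n_tau)
  for (j in 1:2) {
    mu_j <- as.vector(P %*% mu_src[, j])
    v0_j <- as.vector((P^2) %*% s2_src[, j])
    # sum_i (x_ij - mu)^2 = SS - 2 mu S + n mu^2
    SSj <- sum(x[, j]^2); Sj <- sum(x[, j])
    for (t in seq_len(n_tau)) {
      v <- v0_j + taus[t, j]^2
      log_w[, t] <- log_w[, t] - n / 2 * log(2 * pi * v) -
        (SSj - 2 * mu_j * Sj + n * mu_j^2) / (2 * v)
    }
  }
  # Dirichlet(alpha) prior; with alpha = 1 this is flat on the simplex and
  # boundary points are fine (density constant)
  if (alpha != 1) {
    lp <- rowSums((alpha - 1) * log(pmax(P, 1e-300)))
    log_w <- log_w + lp
  }
  w <- exp(log_w - max(log_w))
  wp <- rowSums(w)
  colSums(P * wp) / sum(wp)
}
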