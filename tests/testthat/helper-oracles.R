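# Independent oracles shared across test files.

# Noiseless recording from known per-location kernels with a balanced,
# well-separated (orthogonal) event design whose off-event mean is exactly
# zero, so per-lag OLS with intercept is exact.
orthogonal_ground_truth <- function(n_loc = 4, n_ch = 6, n_events = 9,
                                    fs = 512, seed = 2) {
  set.seed(seed)
  ep <- epoch_grid(-100, 400, fs)
  ev <- lapply(seq_len(n_loc), function(l)
    300 + (l - 1) * 400 + (0:(n_events - 1)) * 1600)
  n <- max(unlist(ev)) + 300
  imp <- matrix(0L, n_loc, n)
  for (l in seq_len(n_loc)) imp[l, ev[[l]]] <- 1L
  x <- seq_along(ep$lags)
  k1 <- sin(2 * pi * x / 50) * exp(-((x - 80) / 40)^2)
  k2 <- cos(2 * pi * x / 70) * exp(-((x - 100) / 50)^2)
  kern <- list(k1, k1, k2, k2)[seq_len(n_loc)]
  mixA <- stats::rnorm(n_ch); mixB <- stats::rnorm(n_ch)
  mix <- cbind(mixA, -mixA, mixB, -mixB)[, seq_len(n_loc), drop = FALSE]
  Y <- matrix(0, n_ch, n)
  for (l in seq_len(n_loc)) for (e in ev[[l]])
    Y[, e + ep$lags] <- Y[, e + ep$lags] + outer(mix[, l], kern[[l]])
  list(rec = eeg_recording(Y, fs), imp = imp, ep = ep, kern = kern, mix = mix)
}

# Closed-form surface potential of a dipole in a homogeneous conducting
# sphere (summed Legendre series).
homogeneous_sphere_potential <- function(R, sigma, r0, m, E) {
  f <- sqrt(sum(r0^2)) / R
  rhat <- if (f > 0) r0 / sqrt(sum(r0^2)) else c(0, 0, 1)
  m_r <- sum(m * rhat)
  tv <- m - m_r * rhat
  m_t <- sqrt(sum(tv^2))
  that <- if (m_t > 0) tv / m_t else c(0, 0, 0)
  x <- pmin(1, pmax(-1, as.numeric(E %*% rhat)))
  ep <- E - outer(x, rhat)
  epn <- sqrt(rowSums(ep^2))
  cphi <- ifelse(epn > 1e-12, as.numeric(ep %*% that) / epn, 0)
  s <- sqrt(pmax(0, 1 - x^2))
  dp <- sqrt(1 - 2 * f * x + f^2)
  rad <- 2 * (x - f) / dp^3 + (1 / f) * (1 / dp - 1)
  tang <- 2 * s / dp^3 + s * (dp + 1) / (dp * (1 - f * x + dp))
  v <- (m_r * rad + m_t * cphi * tang) / (4 * pi * sigma * R^2)
  v - mean(v)
}
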