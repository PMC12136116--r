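# Build a small mvep_estimate directly from a waveform array.
mvep_from_array <- function(W, fs = 512, condition = "pulse",
                            participant = "p1") {
  ep <- epoch_grid(-100, 400, fs)
  stopifnot(dim(W)[3] == length(ep$lags))
  structure(list(waveforms = W, epoch = ep, condition = condition,
                 participant = participant), class = "mvep_estimate")
}

test_that("GFP is the spatial SD, with homogeneity and reference invariance", {
  set.seed(21)
  W <- array(stats::rnorm(8 * 3 * 257), c(8, 3, 257))
  m <- mvep_from_array(W)
  g <- gfp(m, per_location = TRUE)
  # brute-force oracle: population SD across channels
  for (l in 1:3) for (t in c(1, 100, 257)) {
    v <- W[, l, t]
    expect_equal(g$values[l, t], sqrt(mean((v - mean(v))^2)),
                 tolerance = 1e-12)
  }
  # across-location mean
  expect_equal(gfp(m)$values, colMeans(g$values), tolerance = 1e-12)
  # homogeneity: scaling by c scales GFP by |c|
  m2 <- m; m2$waveforms <- -2.5 * W
  expect_equal(gfp(m2)$values, 2.5 * gfp(m)$values, tolerance = 1e-12)
  # adding a spatially uniform offset changes nothing
  m3 <- m; m3$waveforms <- W + 7
  expect_equal(gfp(m3)$values, gfp(m)$values, tolerance = 1e-10)
  # spatially uniform field has zero GFP
  mu <- m; mu$waveforms <- array(3, dim(W))
  expect_lt(max(gfp(mu)$values), 1e-12)
})

test_that("SNR summary reports between-condition GFP and SNR ratios", {
  set.seed(22)
  ep <- epoch_grid(-100, 400, 512)
  t_ms <- ep$times_ms
  sig <- exp(-((t_ms - 85) / 10)^2)       # peaks inside the 80-90 ms window
  topo <- stats::rnorm(16)
  W <- array(0, c(16, 2, length(t_ms)))
  for (l in 1:2) W[, l, ] <- outer(topo, sig)
  noise_amp <- 0.01
  Wa <- W + array(stats::rnorm(length(W), sd = noise_amp), dim(W))
  Wb <- W / 3.2 + array(stats::rnorm(length(W), sd = noise_amp), dim(W))
  s <- snr_summary(mvep_from_array(Wa), mvep_from_array(Wb))
  expect_equal(s$signal_ratio, 3.2, tolerance = 0.05)
  expect_equal(s$baseline_ratio, 1, tolerance = 0.2)
  expect_equal(s$snr_ratio, 3.2, tolerance = 0.6)
  # identical conditions: every ratio is 1
  s1 <- snr_summary(mvep_from_array(Wa), mvep_from_array(Wa))
  expect_equal(unname(c(s1$signal_ratio, s1$baseline_ratio, s1$snr_ratio)),
               c(1, 1, 1), tolerance = 1e-12)
  # noiseless input trips the zero-baseline error
  expect_error(snr_summary(mvep_from_array(W), mvep_from_array(W)),
               "baseline")
})

test_that("topographic cross-correlation is a unit-diagonal symmetric matrix", {
  set.seed(23)
  W <- array(stats::rnorm(6 * 2 * 257), c(6, 2, 257))
  m <- mvep_from_array(W)
  cc <- topographic_crosscorrelation(m)
  expect_equal(dim(cc), c(257L, 257L))
  expect_equal(diag(cc), rep(1, 257))
  expect_equal(cc, t(cc), tolerance = 1e-12)
  # negating one time point negates its row and column
  m2 <- m; m2$waveforms[, , 50] <- -m2$waveforms[, , 50]
  cc2 <- topographic_crosscorrelation(m2)
  expect_equal(cc2[50, -50], -cc[50, -50], tolerance = 1e-12)
  # rank-1 spatiotemporal field: all off-diagonal entries are +/-1
  topo <- stats::rnorm(12)
  wave <- sin(seq(-1, 5, length.out = 257))
  W1 <- array(0, c(12, 1, 257))
  W1[, 1, ] <- outer(topo, wave)
  cc1 <- topographic_crosscorrelation(mvep_from_array(W1))
  expect_equal(abs(cc1[upper.tri(cc1)]), rep(1, sum(upper.tri(cc1))),
               tolerance = 1e-9)
  # zero-variance time point comes back missing, with a log message
  W0 <- W; W0[, , 10] <- 0
  expect_message(cc0 <- topographic_crosscorrelation(mvep_from_array(W0)),
                 "zero spatial variance")
  expect_true(all(is.na(cc0[10, ])))
})

test_that("component detection finds prominent GFP peaks and dips", {
  ep <- epoch_grid(-100, 400, 512)
  t_ms <- ep$times_ms
  y <- exp(-((t_ms - 90) / 14)^2) + 0.8 * exp(-((t_ms - 155) / 18)^2) +
    0.5 * exp(-((t_ms - 240) / 25)^2) + 0.02 * sin(t_ms / 2)
  g <- structure(list(values = y, times_ms = t_ms, per_location = FALSE,
                      condition = "pulse"), class = "gfp_timecourse")
  cs <- find_components(g)
  expect_identical(cs$labels, c("C1", "C2", "C3"))
  expect_equal(cs$latencies_ms, c(90, 155, 240), tolerance = 3)
  expect_true(all(diff(cs$latencies_ms) > 0))
  expect_length(cs$dips_ms, 2L)
  expect_true(cs$dips_ms[1] > 90 && cs$dips_ms[1] < 155)
  # monotone GFP: error listing what was found
  gm <- g; gm$values <- seq_along(t_ms) / 100
  expect_error(find_components(gm), "local maxima")
  # identical twin peaks: both returned, ordered by latency, tie flagged
  yt <- exp(-((t_ms - 100) / 10)^2) + exp(-((t_ms - 200) / 10)^2)
  gt2 <- g; gt2$values <- yt
  cs2 <- find_components(gt2, n_peaks = 2)
  expect_equal(cs2$latencies_ms, c(100, 200), tolerance = 3)
})

test_that("component-pair correlations recover a single-source structure", {
  # one fixed topography, three alternating-polarity phases: all component
  # pattern correlations near +/-1 with signs given by the phase polarity
  set.seed(24)
  ep <- epoch_grid(-100, 400, 512)
  t_ms <- ep$times_ms
  topo <- matrix(stats::rnorm(16 * 4), 16, 4)   # channels x locations
  wave <- exp(-((t_ms - 90) / 14)^2) - 0.8 * exp(-((t_ms - 155) / 18)^2) +
    0.5 * exp(-((t_ms - 240) / 25)^2)
  W <- array(0, c(16, 4, length(t_ms)))
  for (l in 1:4) W[, l, ] <- outer(topo[, l], wave)
  W <- W + array(stats::rnorm(length(W), sd = 1e-4), dim(W))
  m <- mvep_from_array(W)
  cs <- find_components(gfp(m))
  cc <- component_pair_correlations(cs, m, cs, m)
  expect_equal(diag(cc), rep(1, 6), ignore_attr = TRUE)
  within <- cc[1:3, 1:3]
  expect_true(all(abs(within[upper.tri(within)]) > 0.95))
  expect_lt(cc["pulse.C1", "pulse.C2"], 0)   # opposite phase polarity
  expect_gt(cc["pulse.C1", "pulse.C3"], 0)   # same polarity again
})

test_that("dip correlation test: identity gives F near 0, shared source detected", {
  set.seed(25)
  ep <- epoch_grid(-100, 400, 512)
  t_ms <- ep$times_ms
  n_part <- 8
  make_p <- function(shared) {
    c1 <- exp(-((t_ms - 90) / 12)^2)
    dipw <- exp(-((t_ms - 120) / 8)^2)
    topo1 <- matrix(stats::rnorm(16 * 4), 16, 4)
    topo2 <- if (shared) topo1 else matrix(stats::rnorm(16 * 4), 16, 4)
    W <- array(stats::rnorm(16 * 4 * length(t_ms), sd = 0.08),
               c(16, 4, length(t_ms)))
    for (l in 1:4) W[, l, ] <- W[, l, ] + outer(topo1[, l], c1) +
        outer(topo2[, l], 0.5 * dipw)
    mvep_from_array(W)
  }
  shared <- lapply(seq_len(n_part), function(i) make_p(TRUE))
  indep <- lapply(seq_len(n_part), function(i) make_p(FALSE))
  res <- dip_correlation_test(shared, indep, 120, 120,
                              c(85, 95), c(85, 95))
  expect_gt(res$group$mean_r[1], 0.5)            # dip shares the C1 source
  expect_lt(abs(res$group$mean_r[2]), 0.35)      # independent topographies
  expect_lt(res$paired$p, 0.05)                  # conditions differ
  # identical conditions: paired F collapses to 0
  res0 <- dip_correlation_test(shared, shared, 120, 120,
                               c(85, 95), c(85, 95))
  expect_lt(res0$paired$F, 1e-12)
  expect_error(dip_correlation_test(shared[1], indep[1], 120, 120,
                                    c(85, 95), c(85, 95)), "participants")
})

test_that("area/component/location correlations flag the matching area", {
  sm <- fix_small()
  pm <- sm$pm
  n_loc <- dim(pm$values)[2]
  # a component that equals one area's predictions at every location
  topo <- array(0, c(dim(pm$values)[3], n_loc, 2))
  for (l in seq_len(n_loc)) {
    topo[, l, 1] <- pm$values[pm$area_names[1], l, ]
    v <- pm$values[pm$area_names[2], l, ]
    # orthogonalize component 2 against area 1's prediction (Gram-Schmidt)
    a <- pm$values[pm$area_names[1], l, ]
    topo[, l, 2] <- v - sum(v * a) / sum(a * a) * a
  }
  res <- area_component_location_correlations(topo, pm,
                                              c("match", "ortho"))
  expect_equal(as.numeric(res$r[pm$area_names[1], "match", ]),
               rep(1, n_loc), tolerance = 1e-9)
  expect_identical(unname(res$best_area["match"]), pm$area_names[1])
  expect_lt(abs(res$mean_r[pm$area_names[1], "ortho"]), 0.05)
  expect_true(res$sign_consistent[pm$area_names[1], "match"])
})
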