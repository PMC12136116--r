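local_extrema <- function(k, t_ms) {
  idx <- which(diff(sign(diff(k))) != 0) + 1L
  idx <- idx[abs(k[idx]) > 0.05 * max(abs(k))]
  data.frame(t = t_ms[idx], v = k[idx])
}

test_that("source kernels carry the injected component structure", {
  ep <- epoch_grid()
  cfg <- simulation_config()
  kp <- make_source_kernels("pulse", ep, cfg)
  # pulse V1: three extrema near 90/155/240 ms with alternating signs
  ex <- local_extrema(kp$V1, ep$times_ms)
  expect_identical(nrow(ex), 3L)
  expect_equal(ex$t, c(90, 155, 240), tolerance = 2)
  expect_identical(sign(ex$v), c(1, -1, 1))
  # V1 dominates every extrastriate kernel at least two-fold
  for (a in setdiff(names(kp), "V1"))
    expect_gte(max(abs(kp$V1)), 2 * max(abs(kp[[a]])))
  # extrastriate first-phase signs are mixed
  first_sign <- vapply(kp[-1], function(k) sign(k[which.max(abs(k))]),
                       numeric(1))
  expect_true(any(first_sign > 0) && any(first_sign < 0))
  # kernels vanish outside 0-350 ms
  outside <- ep$times_ms < 0 | ep$times_ms > 350
  for (k in kp) expect_true(all(k[outside] == 0))

  # reversal V1: biphasic, first extremum delayed 50 +/- 2 ms
  kr <- make_source_kernels("reversal", ep, cfg)
  exr <- local_extrema(kr$V1, ep$times_ms)
  expect_identical(nrow(exr), 2L)
  expect_equal(exr$t[1] - ex$t[1], 50, tolerance = 2)
  # the condition scale ratio divides the whole condition
  expect_equal(max(abs(kr$V1)) * 3.2, max(abs(kp$V1)), tolerance = 0.01)
  # zero amplitude map -> all-zero kernels
  cfg0 <- simulation_config(condition_scale = c(pulse = 0, reversal = 0))
  expect_true(all(vapply(make_source_kernels("pulse", ep, cfg0),
                         function(k) all(k == 0), logical(1))))
})

test_that("simulation is deterministic under a fixed seed", {
  rd <- fix_reduced()
  s1 <- simulate_participant(rd$cfg, rd$train, rd$pm, rd$kernels$pulse,
                             rd$epoch, rd$mon, 99, rd$comps$pulse)
  s2 <- simulate_participant(rd$cfg, rd$train, rd$pm, rd$kernels$pulse,
                             rd$epoch, rd$mon, 99, rd$comps$pulse)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$ground_truth$gain, s2$ground_truth$gain)
  s3 <- simulate_participant(rd$cfg, rd$train, rd$pm, rd$kernels$pulse,
                             rd$epoch, rd$mon, 100, rd$comps$pulse)
  expect_gt(max(abs(s3$recording$data - s1$recording$data)), 0)
})

test_that("noiseless closed loop recovers injected beta profiles", {
  # a well-separated (orthogonal) event design so per-lag OLS is exact;
  # every area drives every location through its predicted topography
  pm <- fix_predictions()
  ep <- epoch_grid(fs = 512)
  cfg <- simulation_config(n_participants = 1, noise_amplitude = 0,
                           gain_sd = 0, jitter_sd_ms = 0)
  kern <- make_source_kernels("pulse", ep, cfg)
  n_loc <- 16
  ev <- lapply(seq_len(n_loc), function(l)
    600 + (l - 1) * 300 + (0:5) * 5200)
  n <- max(unlist(ev)) + 400
  imp <- matrix(0L, n_loc, n)
  for (l in seq_len(n_loc)) imp[l, ev[[l]]] <- 1L
  Y <- matrix(0, 128, n)
  for (l in seq_len(n_loc)) {
    chans <- sapply(names(kern), function(a) pm$values[a, l, ])  # 128 x 8
    ktab <- sapply(kern, identity)                               # lags x 8
    resp <- chans %*% t(ktab)                                    # 128 x lags
    for (e in ev[[l]]) Y[, e + ep$lags] <- Y[, e + ep$lags] + resp
  }
  est <- estimate_mvep(eeg_recording(Y, 512), imp, ep)
  fit <- rcse_fit(est, pm)
  wg <- window_grid()
  A <- mfvep:::window_average_matrix(ep$times_ms, wg)
  for (a in names(kern)) {
    inj <- as.numeric(kern[[a]] %*% A)
    expect_gt(stats::cor(fit$full_betas[a, ], inj), 0.999)
  }
})

test_that("study simulation matches the declared design and manifest", {
  cfg <- simulation_config(n_participants = 2, n_channels = 16,
                           n_locations = 4, n_repetitions = 1, seed = 5)
  mon <- default_montage(16)
  hm <- head_model()
  sig <- default_area_signatures()[c(1, 4), ]
  pm <- suppressWarnings(build_prediction_matrix(
    retinotopic_patches(hm, n_wedges = 4, signatures = sig), hm, mon))
  tr <- build_pulse_train(
    thin_pulse_stream(rotate_to_run_boundary(generate_msequence(9)$bits)),
    n_locations = 4)
  kernsub <- function(cond) {
    k <- make_source_kernels(cond, epoch_grid(fs = cfg$fs), cfg)
    out <- k[c("V1", "V4")]
    attr(out, "scale") <- attr(k, "scale")
    out
  }
  kerns <- list(pulse = kernsub("pulse"), reversal = kernsub("reversal"))
  st <- simulate_study(cfg, train = tr, predictions = pm, montage = mon,
                       reduce = function(rec, cond, p) dim(rec$data),
                       kernels = kerns)
  expect_length(st$results, 2L)
  expect_named(st$results[[1]], c("pulse", "reversal"))
  expect_identical(nrow(st$manifest), 4L)
  expect_true(all(st$manifest$seed > 0))
  # rerunning with the same master seed reproduces the manifest
  st2 <- simulate_study(cfg, train = tr, predictions = pm, montage = mon,
                        reduce = function(rec, cond, p) sum(rec$data^2),
                        kernels = kerns)
  expect_identical(st$manifest$seed, st2$manifest$seed)
})

test_that("halving the noise roughly doubles the signal-to-baseline GFP ratio", {
  rd <- fix_reduced()
  ratio_at <- function(noise_amp, seed) {
    cfg <- rd$cfg
    cfg$noise_amplitude <- noise_amp
    ests <- lapply(1:3, function(p) {
      sim <- simulate_participant(cfg, rd$train, rd$pm, rd$kernels$pulse,
                                  rd$epoch, rd$mon, seed + p,
                                  rd$comps$pulse)
      estimate_mvep(sim$recording, rd$imp, rd$epoch, design = rd$design)
    })
    g <- gfp(grand_average(ests))
    window_mean(g$values, g$times_ms, c(80, 90)) /
      window_mean(g$values, g$times_ms, c(-50, 0))
  }
  r_full <- ratio_at(20, 700)
  r_half <- ratio_at(10, 700)
  expect_gt(r_half / r_full, 1.4)
  expect_lt(r_half / r_full, 2.8)
})

test_that("preprocessing chain preserves deconvolved waveforms", {
  # noiseless reduced-scale participant: the full conditioning chain
  # (low-pass, detrend, average reference) must leave the deconvolved
  # evoked waveforms nearly unchanged
  rd <- fix_reduced()
  cfg <- rd$cfg
  cfg$noise_amplitude <- 0
  cfg$gain_sd <- 0
  cfg$jitter_sd_ms <- 0
  sim <- simulate_participant(cfg, rd$train, rd$pm, rd$kernels$pulse,
                              rd$epoch, rd$mon, 1, rd$comps$pulse)
  raw <- estimate_mvep(sim$recording, rd$imp, rd$epoch, design = rd$design)
  h <- design_windowed_sinc(77, cfg$fs, 35.3)
  rel_rms <- function(rec) {
    est <- estimate_mvep(rec, rd$imp, rd$epoch, design = rd$design)
    sqrt(mean((est$waveforms - raw$waveforms)^2)) /
      sqrt(mean(raw$waveforms^2))
  }
  # the low-pass stage alone is transparent to the band-limited waveforms
  expect_lt(rel_rms(apply_filter(sim$recording, h)), 0.02)
  # adding 0.5-s piecewise detrending removes some in-band energy but
  # leaves the waveform shape essentially intact
  cleaned <- average_reference(piecewise_detrend(apply_filter(sim$recording, h)))
  expect_lt(rel_rms(cleaned), 0.05)
  est <- estimate_mvep(cleaned, rd$imp, rd$epoch, design = rd$design)
  expect_gt(stats::cor(as.vector(est$waveforms), as.vector(raw$waveforms)),
            0.998)
})
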