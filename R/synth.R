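# Forward-model EEG simulator: multi-participant synthetic recordings with
# the statistical structure the multifocal analysis assumes, retaining
# ground truth for parameter-recovery tests.

#' Simulation configuration
#'
#' Defaults emulate the reference study design: 13 participants, 128
#' channels at 512 Hz, 16 wedge locations, 10 repetitions of a thinned
#' degree-11 pulse train at 40 frames/s, two conditions. The pulse condition
#' carries a dominant triphasic V1 source (peaks near 90/155/240 ms); the
#' reversal condition an extrastriate-first response with a biphasic V1
#' source delayed by 50 ms and the whole condition scaled down by the
#' condition scale ratio (3.2).
#'
#' @param n_participants Number of participants (default 13).
#' @param n_channels Electrodes (default 128).
#' @param fs Sampling rate Hz (default 512).
#' @param n_locations Stimulus wedges (default 16).
#' @param n_repetitions Pulse-train repetitions (default 10).
#' @param condition_scale Named amplitude scale per condition; the default
#'   pulse:reversal ratio is 3.2:1.
#' @param source_scale Moment scale converting unit kernels to recording
#'   units (µV-scale given the forward model's arbitrary-unit topographies).
#' @param noise_amplitude Sensor-noise RMS in the same units (µV).
#' @param noise_spectrum Temporal noise spectrum: "pink" (approximately
#'   1/f, via cascaded first-order sections) or "white".
#' @param noise_lambda Angular length scale (radians) of the spatial noise
#'   correlation over the scalp.
#' @param gain_sd SD of the per-participant multiplicative gain (mean 1).
#' @param jitter_sd_ms SD of the per-participant latency jitter.
#' @param v1_delay_ms Delay of the reversal V1 response relative to the
#'   pulse V1 response (default 50 ms).
#' @param seed Master seed recorded in all outputs.
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_participants = 13L, n_channels = 128L,
                              fs = 512, n_locations = 16L,
                              n_repetitions = 10L,
                              condition_scale = c(pulse = 1,
                                                  reversal = 1 / 3.2),
                              source_scale = 5e4,
                              noise_amplitude = 20,
                              noise_spectrum = "pink",
                              noise_lambda = 0.6,
                              gain_sd = 0.2, jitter_sd_ms = 5,
                              v1_delay_ms = 50,
                              seed = 1L) {
  stopifnot(n_participants >= 1, n_channels >= 2, fs > 0,
            n_locations >= 1, n_repetitions >= 1)
  structure(list(n_participants = as.integer(n_participants),
                 n_channels = as.integer(n_channels), fs = fs,
                 n_locations = as.integer(n_locations),
                 n_repetitions = as.integer(n_repetitions),
                 condition_scale = condition_scale,
                 source_scale = source_scale,
                 noise_amplitude = noise_amplitude,
                 noise_spectrum = noise_spectrum,
                 noise_lambda = noise_lambda,
                 gain_sd = gain_sd, jitter_sd_ms = jitter_sd_ms,
                 v1_delay_ms = v1_delay_ms,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

gauss_lobe <- function(t_ms, mu, sd, amp) amp * exp(-((t_ms - mu) / sd)^2)

# invented lobe tables (documented defaults): only peak latencies and the
# qualitative structure are anchored to the reference waveforms
kernel_lobes <- function(condition, v1_delay_ms = 50) {
  if (condition == "pulse") {
    list(
      V1  = rbind(c(90, 15, 1.00), c(155, 20, -0.90), c(240, 30, 0.55)),
      V2  = rbind(c(95, 20, 0.42), c(165, 28, -0.22)),
      V3  = rbind(c(100, 20, -0.40), c(175, 28, 0.20)),
      V4  = rbind(c(105, 22, 0.30)),
      TO1 = rbind(c(85, 16, -0.28)),
      TO2 = rbind(c(88, 16, 0.22)),
      LO1 = rbind(c(100, 20, -0.30)),
      LO2 = rbind(c(108, 22, 0.20)))
  } else {
    d <- v1_delay_ms
    list(
      V1  = rbind(c(90 + d, 18, 1.00), c(155 + d, 24, -0.85)),
      V2  = rbind(c(85, 20, 0.90), c(150, 26, -0.18)),
      V3  = rbind(c(90, 20, -0.85)),
      V4  = rbind(c(98, 22, 0.40)),
      TO1 = rbind(c(78, 16, -0.35)),
      TO2 = rbind(c(80, 16, 0.28)),
      LO1 = rbind(c(93, 20, -0.40)),
      LO2 = rbind(c(100, 22, 0.28)))
  }
}

#' Construct per-area source kernels
#'
#' Sums of Gaussian-windowed lobes on the epoch grid, zero outside
#' 0--350 ms. Pulse: triphasic V1 (alternating polarity, peaks near
#' 90/155/240 ms) at twice or more the amplitude of any extrastriate
#' kernel, extrastriate kernels mixed-sign in the first phase. Reversal:
#' extrastriate kernels lead, V1 is biphasic and starts
#' `config$v1_delay_ms` later than in the pulse condition, and the whole
#' condition is scaled by the condition scale ratio.
#'
#' @param condition "pulse" or "reversal".
#' @param epoch An [epoch_grid()].
#' @param config A [simulation_config()].
#' @return Named list of kernels (numeric vectors over the epoch grid) with
#'   attribute `"scale"` (applied condition scale).
#' @export
make_source_kernels <- function(condition = c("pulse", "reversal"),
                                epoch = epoch_grid(),
                                config = simulation_config()) {
  condition <- match.arg(condition)
  t_ms <- epoch$times_ms
  supp <- as.numeric(t_ms >= 0 & t_ms <= 350)
  scl <- config$condition_scale[[condition]]
  lobes <- kernel_lobes(condition, config$v1_delay_ms)
  kerns <- lapply(lobes, function(tab) {
    k <- numeric(length(t_ms))
    for (i in seq_len(nrow(tab)))
      k <- k + gauss_lobe(t_ms, tab[i, 1], tab[i, 2], tab[i, 3])
    k * supp * scl
  })
  attr(kerns, "scale") <- scl
  kerns
}

# Spatial noise-mixing operator: truncated eigenbasis factor of a smooth
# angular correlation kernel over the electrode sphere (the kernel is
# effectively low-rank; modes capturing 99.5% of its trace are kept). Rows
# are scaled so every channel has unit marginal variance.
noise_mixing <- function(montage, lambda) {
  P <- montage$positions
  ang <- acos(pmin(pmax(P %*% t(P), -1), 1))
  C <- exp(-0.5 * (ang / lambda)^2)
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(cumsum(eg$values) / sum(eg$values) >= 0.995)[1L]
  L <- eg$vectors[, seq_len(keep), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(keep)]), keep)
  L / sqrt(rowSums(L^2))
}

# Temporally shaped Gaussian noise, n_src x n, unit RMS per source.
# "pink" approximates a 1/f spectrum by summing three first-order recursive
# sections with staggered poles (the standard cascaded-AR pink generator);
# "white" returns the unfiltered draws.
shaped_noise <- function(n_src, n, fs, spectrum = "pink") {
  W <- matrix(stats::rnorm(n_src * n), n, n_src)
  if (spectrum == "pink") {
    Z <- 0.0990 * unclass(stats::filter(W, 0.99765, method = "recursive")) +
      0.2965 * unclass(stats::filter(W, 0.96300, method = "recursive")) +
      1.0527 * unclass(stats::filter(W, 0.57000, method = "recursive")) +
      0.1848 * W
  } else if (spectrum == "white") {
    Z <- W
  } else stop("unknown noise spectrum: ", spectrum)
  Z <- sweep(Z, 2, apply(Z, 2, stats::sd), "/")
  t(Z)
}

#' Simulate one participant's recording for one condition
#'
#' Signal: for every area and location, the location's event impulses are
#' convolved with the area kernel (shifted by the participant's latency
#' jitter and scaled by the participant's gain) and projected through the
#' area x location scalp topography; responses never cross repetition-block
#' boundaries. Noise: spatially correlated (smooth angular kernel over the
#' scalp) Gaussian noise with an approximately 1/f ("pink") spectrum. The
#' recording is average-referenced.
#'
#' @param config A [simulation_config()].
#' @param train A `pulse_train`.
#' @param predictions A `prediction_matrix` covering all kernel areas.
#' @param kernels Kernels from [make_source_kernels()].
#' @param epoch The [epoch_grid()] the kernels live on.
#' @param montage The electrode montage (for the spatial noise kernel).
#' @param participant_seed Integer seed for this participant's gain, jitter
#'   and noise.
#' @param components Optional precomputed [signal_components()] for this
#'   (train, predictions, kernels) triple; pass one when simulating many
#'   participants to avoid recomputing the shared noiseless response.
#' @return List with `recording` (an [eeg_recording()]) and `ground_truth`
#'   (gain, jitter_ms, seed, kernels, condition scale).
#' @export
simulate_participant <- function(config, train, predictions, kernels,
                                 epoch = epoch_grid(fs = config$fs),
                                 montage = NULL, participant_seed = 1L,
                                 components = NULL) {
  if (is.null(components))
    components <- signal_components(config, train, predictions, kernels,
                                    epoch)
  set.seed(as.integer(participant_seed))
  gain <- 1 + stats::rnorm(1, 0, config$gain_sd)
  jitter_ms <- stats::rnorm(1, 0, config$jitter_sd_ms)
  jit <- as.integer(round(jitter_ms / 1000 * config$fs))

  # latency jitter: rigid within-block shift of the noiseless response
  E <- components$E
  blocks <- components$blocks
  if (jit != 0L) {
    Es <- matrix(0, nrow(E), ncol(E))
    ends <- cumsum(blocks)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (b in seq_along(blocks)) {
      src <- (starts[b]:ends[b]) - jit
      ok <- src >= starts[b] & src <= ends[b]
      Es[(starts[b]:ends[b])[ok], ] <- E[src[ok], , drop = FALSE]
    }
    E <- Es
  }
  signal <- (config$source_scale * gain) * (components$P %*% t(E))

  if (is.null(montage))
    montage <- structure(list(labels = predictions$channel_labels,
                              positions = default_montage(config$n_channels)$positions),
                         class = "electrode_montage")
  L <- noise_mixing(montage, config$noise_lambda)
  noise <- config$noise_amplitude *
    (L %*% shaped_noise(ncol(L), ncol(signal), config$fs,
                        config$noise_spectrum))
  rec <- eeg_recording(signal + noise, config$fs,
                       labels = predictions$channel_labels, blocks = blocks)
  rec <- average_reference(rec)
  list(recording = rec,
       ground_truth = list(gain = gain, jitter_ms = jitter_ms,
                           seed = as.integer(participant_seed),
                           kernels = kernels,
                           scale = attr(kernels, "scale")))
}

#' Shared noiseless response components of a simulated condition
#'
#' Convolves every location's event impulses with every area kernel
#' (block-wise, so responses never cross repetition boundaries) and collects
#' the area x location scalp projection matrix. The result depends only on
#' the train, predictions and kernels, so it can be shared across simulated
#' participants.
#'
#' @inheritParams simulate_participant
#' @return List with `E` (samples x (area, location) response courses), `P`
#'   (channels x (area, location) topographies), `blocks`, `areas`.
#' @export
signal_components <- function(config, train, predictions, kernels,
                              epoch = epoch_grid(fs = config$fs)) {
  areas <- names(kernels)
  if (!all(areas %in% predictions$area_names))
    stop("prediction matrix lacks areas: ",
         paste(setdiff(areas, predictions$area_names), collapse = ", "))
  if (dim(predictions$values)[3] != config$n_channels)
    stop("prediction matrix channel count does not match the config")
  fs <- config$fs
  imp <- resample_events(train, fs)
  ev <- attr(imp, "event_samples")
  n <- ncol(imp)
  per_rep <- train$period * fs / train$frame_rate
  bounds <- round(per_rep * seq_len(train$n_repetitions))
  bounds[length(bounds)] <- n
  blocks <- as.integer(diff(c(0, bounds)))
  lags <- epoch$lags
  n_loc <- nrow(imp)
  E <- matrix(0, n, length(areas) * n_loc)   # samples x (area, location)
  bstart <- c(0L, bounds[-length(bounds)])
  for (b in seq_along(blocks)) {
    rng <- (bstart[b] + 1L):bounds[b]
    nb <- length(rng)
    pad <- stats::nextn(nb + length(lags), c(2L, 3L, 5L))
    fk <- lapply(kernels, function(k) {
      kk <- numeric(pad)
      # place the kernel with its negative lags wrapped to the pad tail
      kk[(lags %% pad) + 1L] <- k
      stats::fft(kk)
    })
    for (l in seq_len(n_loc)) {
      e_in <- ev[[l]][ev[[l]] >= rng[1] & ev[[l]] <= rng[nb]] - bstart[b]
      if (!length(e_in)) next
      delta <- numeric(pad)
      delta[e_in] <- 1
      fd <- stats::fft(delta)
      for (a in seq_along(areas)) {
        resp <- Re(stats::fft(fd * fk[[a]], inverse = TRUE)) / pad
        col <- (a - 1L) * n_loc + l
        E[rng, col] <- E[rng, col] + resp[seq_len(nb)]
      }
    }
  }
  P <- matrix(0, config$n_channels, length(areas) * n_loc)
  for (a in seq_along(areas)) for (l in seq_len(n_loc))
    P[, (a - 1L) * n_loc + l] <- predictions$values[areas[a], l, ]
  list(E = E, P = P, blocks = blocks, areas = areas)
}

#' Simulate a full multi-participant study
#'
#' Builds the default stimulus train and prediction matrix (unless
#' supplied), generates both conditions for every participant with
#' independent seeds derived from the master seed, and applies `reduce` to
#' every recording (by default the recording itself is kept; passing e.g. a
#' deconvolution step keeps memory flat for full-scale studies).
#'
#' @param config A [simulation_config()].
#' @param train Optional `pulse_train` (default: designed from the config).
#' @param predictions Optional `prediction_matrix` (default: built-in
#'   retinotopy).
#' @param montage Optional montage (default deterministic 128-channel).
#' @param reduce Function `(recording, condition, participant)` applied to
#'   each simulated recording; its value is stored instead.
#' @param kernels Optional named list with elements `pulse` and `reversal`
#'   overriding [make_source_kernels()] (e.g. to restrict the simulated
#'   areas).
#' @return List with `results` (per participant, per condition), `ground_truth`,
#'   `train`, `predictions`, `config`, `manifest` (seed table).
#' @export
simulate_study <- function(config = simulation_config(), train = NULL,
                           predictions = NULL, montage = NULL,
                           reduce = NULL, kernels = NULL) {
  if (is.null(train))
    train <- design_pulse_train(n_locations = config$n_locations,
                                n_repetitions = config$n_repetitions,
                                seed = config$seed)
  if (is.null(montage)) montage <- default_montage(config$n_channels)
  if (is.null(predictions)) {
    hm <- head_model()
    predictions <- build_prediction_matrix(
      retinotopic_patches(hm, n_wedges = config$n_locations), hm, montage)
  }
  if (is.null(reduce)) reduce <- function(rec, condition, participant) rec
  epoch <- epoch_grid(fs = config$fs)
  conditions <- c("pulse", "reversal")
  if (is.null(kernels)) {
    kerns <- lapply(conditions, make_source_kernels, epoch = epoch,
                    config = config)
    names(kerns) <- conditions
  } else {
    if (!all(conditions %in% names(kernels)))
      stop("`kernels` must provide both conditions")
    kerns <- kernels[conditions]
  }
  comps <- lapply(kerns, function(k)
    signal_components(config, train, predictions, k, epoch))
  set.seed(config$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             config$n_participants * 2L),
                  config$n_participants, 2L,
                  dimnames = list(NULL, conditions))
  results <- vector("list", config$n_participants)
  gt <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    res_p <- list()
    gt_p <- list()
    for (cond in conditions) {
      sim <- simulate_participant(config, train, predictions, kerns[[cond]],
                                  epoch, montage, seeds[p, cond],
                                  components = comps[[cond]])
      res_p[[cond]] <- reduce(sim$recording, cond, p)
      gt_p[[cond]] <- sim$ground_truth
    }
    results[[p]] <- res_p
    gt[[p]] <- gt_p
  }
  list(results = results, ground_truth = gt, train = train,
       predictions = predictions, config = config,
       manifest = data.frame(participant = rep(seq_len(config$n_participants),
                                               each = 2L),
                             condition = rep(conditions,
                                             config$n_participants),
                             seed = as.vector(t(seeds))))
}
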