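# Deconvolution of per-location mVEP waveforms by lagged regression of the
# EEG against the multi-location pulse matrix.

#' Epoch grid for deconvolved waveforms
#'
#' @param start_ms Epoch start relative to the event (default -100 ms).
#' @param end_ms Epoch end (default 400 ms).
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{"epoch_grid"} with `lags` (sample lags,
#'   lag 0 = event onset) and `times_ms`.
#' @export
epoch_grid <- function(start_ms = -100, end_ms = 400, fs = 512) {
  if (!(start_ms < 0 && 0 < end_ms)) stop("epoch must straddle 0 ms")
  lags <- seq(round(start_ms / 1000 * fs), round(end_ms / 1000 * fs))
  structure(list(lags = as.integer(lags), times_ms = lags / fs * 1000,
                 fs = fs, start_ms = start_ms, end_ms = end_ms),
            class = "epoch_grid")
}

#' Resample a pulse train to the EEG sampling grid
#'
#' Each stimulation event becomes a unit impulse at the EEG sample nearest
#' its frame-onset time. At 512 Hz and 40 frames/s one frame spans 12.8
#' samples, so rounding jitter is below 1 ms and no two events can collide
#' on the same sample.
#'
#' @param train A `pulse_train`.
#' @param fs EEG sampling rate in Hz (must be at least the frame rate).
#' @return locations x samples 0/1 impulse matrix; attribute
#'   `"event_samples"` holds the per-location event sample indices (1-based).
#' @export
resample_events <- function(train, fs) {
  stopifnot(inherits(train, "pulse_train"))
  if (fs < train$frame_rate) stop("`fs` must be at least the frame rate")
  n_frames <- ncol(train$events)
  n_samples <- ceiling(n_frames * fs / train$frame_rate)
  idx_list <- lapply(seq_len(nrow(train$events)), function(l) {
    fr <- which(train$events[l, ] == 1L) - 1L         # 0-based frame index
    smp <- as.integer(round(fr * fs / train$frame_rate)) + 1L  # nearest sample, 1-based
    if (anyDuplicated(smp))
      stop("two events in location ", l, " mapped to the same sample")
    smp
  })
  out <- matrix(0L, nrow(train$events), n_samples)
  for (l in seq_along(idx_list)) out[l, idx_list[[l]]] <- 1L
  attr(out, "event_samples") <- idx_list
  out
}

#' Estimate per-location mVEP waveforms by lagged regression
#'
#' For every epoch lag, each EEG channel is regressed (ordinary least
#' squares, with intercept) on the impulse matrix shifted by that lag; the
#' per-location coefficients at lag tau form the waveform value at time
#' tau. Shifted regressors are zeroed outside their own recording block, so
#' no epoch leaks across acquisition breaks. Because the location streams
#' are mutually uncorrelated by design, the joint regression unmixes the
#' overlapping responses of all 16 locations.
#'
#' @param rec An [eeg_recording()] aligned sample-for-sample with the
#'   impulse matrix.
#' @param impulses locations x samples impulse matrix from
#'   [resample_events()] (or any 0/1 matrix of matching width).
#' @param epoch An [epoch_grid()] (its `fs` must match the recording).
#' @return An object of class \code{"mvep_estimate"}: list with `waveforms`
#'   (channels x locations x epoch samples), `epoch`, `condition`,
#'   `participant`.
#' @param condition Condition tag carried through ("pulse" or "reversal").
#' @param participant Participant identifier carried through.
#' @param design Optional precomputed [deconv_design()]; pass one when
#'   estimating many recordings that share the same pulse train, block
#'   structure and epoch (the per-lag normal equations are then factored
#'   only once).
#' @export
estimate_mvep <- function(rec, impulses, epoch = epoch_grid(fs = rec$fs),
                          condition = "pulse", participant = "p1",
                          design = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (epoch$fs != rec$fs) stop("epoch and recording sampling rates differ")
  n <- ncol(rec$data)
  if (is.null(design))
    design <- deconv_design(impulses, epoch, rec$blocks)
  if (design$n_samples != n)
    stop("design and recording sample counts differ")
  n_loc <- design$n_locations
  n_lag <- length(epoch$lags)
  n_ch <- nrow(rec$data)
  # per-channel event-locked sums for every (location, lag) at once
  B_all <- as.matrix(rec$data %*% design$X)     # channels x (loc, lag)
  ysum <- rowSums(rec$data)
  W <- array(NA_real_, dim = c(n_ch, n_loc, n_lag),
             dimnames = list(rec$labels, paste0("loc", seq_len(n_loc)),
                             NULL))
  for (t_i in seq_len(n_lag)) {
    cols <- (t_i - 1L) * n_loc + seq_len(n_loc)
    B <- rbind(t(B_all[, cols, drop = FALSE]), ysum)
    beta <- solve(design$qrA[[t_i]], B)
    W[, , t_i] <- t(beta[seq_len(n_loc), , drop = FALSE])
  }
  structure(list(waveforms = W, epoch = epoch, condition = condition,
                 participant = participant),
            class = "mvep_estimate")
}

#' Precompute the lagged-regression design
#'
#' Builds, for every epoch lag, the shifted event indicators (clipped to
#' their own recording block) and the factored normal equations of the
#' per-lag OLS. The result depends only on the pulse train, the block
#' structure and the epoch, so it can be shared across recordings.
#'
#' @param impulses locations x samples 0/1 impulse matrix (ideally from
#'   [resample_events()], whose event-sample attribute is reused).
#' @param epoch An [epoch_grid()].
#' @param blocks Integer vector of block lengths (summing to the sample
#'   count the recordings will have).
#' @return Object of class \code{"deconv_design"}.
#' @export
deconv_design <- function(impulses, epoch, blocks = ncol(impulses)) {
  n <- sum(blocks)
  if (ncol(impulses) > n) stop("impulse matrix is wider than the recording")
  n_loc <- nrow(impulses)
  ev <- attr(impulses, "event_samples")
  if (is.null(ev))
    ev <- lapply(seq_len(n_loc), function(l) which(impulses[l, ] == 1L))
  ends <- cumsum(blocks)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  n_blk <- length(blocks)
  blk_of <- function(x) findInterval(x, starts)
  # per-pair co-occurrence samples, pre-split by block and sorted: a joint
  # shift by tau moves them rigidly, so per-lag counts are two
  # findInterval() lookups per block
  pair_split <- list()
  for (i in seq_len(n_loc)) for (j in i:n_loc) {
    p <- if (i == j) ev[[i]] else intersect(ev[[i]], ev[[j]])
    pair_split[[paste(i, j)]] <- split(p, blk_of(p))
  }
  count_pair <- function(key, tau) {
    s <- 0L
    for (bname in names(pair_split[[key]])) {
      b <- as.integer(bname)
      v <- pair_split[[key]][[bname]]
      lo <- starts[b] - tau; hi <- ends[b] - tau
      s <- s + sum(findInterval(c(lo - 1L, hi), v) %*% c(-1L, 1L))
    }
    s
  }
  n_lag <- length(epoch$lags)
  # sparse shifted-indicator design, columns ordered (lag-major, location)
  trip_i <- vector("list", n_lag * n_loc)
  trip_j <- vector("list", n_lag * n_loc)
  counts <- matrix(0L, n_loc, n_lag)
  evb <- lapply(ev, blk_of)
  for (t_i in seq_len(n_lag)) {
    tau <- epoch$lags[t_i]
    for (i in seq_len(n_loc)) {
      idx <- ev[[i]] + tau
      keep <- idx >= 1L & idx <= n
      keep[keep] <- blk_of(idx[keep]) == evb[[i]][keep]
      idx <- idx[keep]
      col <- (t_i - 1L) * n_loc + i
      trip_i[[col]] <- idx
      trip_j[[col]] <- rep.int(col, length(idx))
      counts[i, t_i] <- length(idx)
    }
  }
  X <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = 1, dims = c(n, n_lag * n_loc))
  qrA <- vector("list", n_lag)
  for (t_i in seq_len(n_lag)) {
    tau <- epoch$lags[t_i]
    A <- matrix(0, n_loc + 1L, n_loc + 1L)
    for (i in seq_len(n_loc)) {
      for (j in i:n_loc)
        A[i, j] <- A[j, i] <- count_pair(paste(i, j), tau)
      A[i, i] <- A[i, n_loc + 1L] <- A[n_loc + 1L, i] <- counts[i, t_i]
    }
    A[n_loc + 1L, n_loc + 1L] <- n
    qa <- qr(A)
    if (qa$rank < ncol(A)) {
      dep <- setdiff(seq_len(n_loc), qa$pivot[seq_len(qa$rank)])
      stop("rank-deficient design at lag ", tau, "; collinear locations: ",
           paste(dep, collapse = ", "))
    }
    qrA[[t_i]] <- qa
  }
  structure(list(X = X, qrA = qrA, n_samples = n, n_locations = n_loc,
                 epoch = epoch, blocks = as.integer(blocks)),
            class = "deconv_design")
}

#' @export
print.mvep_estimate <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf(
    "<mvep_estimate> %s / %s: %d channels x %d locations x %d epoch samples (%g..%g ms)\n",
    x$condition, x$participant, d[1], d[2], d[3],
    x$epoch$start_ms, x$epoch$end_ms))
  invisible(x)
}

#' Grand-average mVEP across participants
#'
#' @param estimates List of `mvep_estimate` objects with identical shapes
#'   and epochs.
#' @return `mvep_estimate` with element-wise mean waveforms and participant
#'   id "grand".
#' @export
grand_average <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  d <- dim(estimates[[1L]]$waveforms)
  for (e in estimates) {
    if (!identical(dim(e$waveforms), d))
      stop("waveform shape mismatch across participants")
    if (!identical(e$epoch$lags, estimates[[1L]]$epoch$lags))
      stop("epoch mismatch across participants")
  }
  acc <- Reduce(`+`, lapply(estimates, function(e) e$waveforms))
  out <- estimates[[1L]]
  out$waveforms <- acc / length(estimates)
  out$participant <- "grand"
  out
}
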