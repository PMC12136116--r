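# Maximal-length sequence generation, pulse thinning and multi-location
# pulse-train construction for multifocal stimulation.

#' Generate one period of a maximal-length binary sequence
#'
#' Runs a Fibonacci linear-feedback shift register (LFSR) of the given degree
#' and returns one full period of its output. A maximal-length sequence
#' (m-sequence) of degree \eqn{k} has period \eqn{2^k - 1}, contains exactly
#' \eqn{2^{k-1}} ones, and its \eqn{\pm 1}-mapped periodic autocorrelation is
#' \eqn{-1/(2^k-1)} at every nonzero cyclic lag — the near-zero
#' cross-correlation that multifocal stimulus designs rely on.
#'
#' @param degree Register length \eqn{k \ge 2}; the period is \eqn{2^k - 1}.
#' @param taps Feedback tap positions (a subset of \code{1:degree} that must
#'   include \code{degree}), corresponding to a primitive polynomial over
#'   GF(2). Defaults to a known primitive set for degrees 2--16.
#' @param init_state Initial register state, a binary vector of length
#'   \code{degree} with at least one 1. Defaults to \code{c(1, 0, 0, ...)}.
#' @return An object of class \code{"msequence"}: a list with elements
#'   \code{bits} (integer 0/1 vector of length \eqn{2^k-1}), \code{degree},
#'   \code{taps} and \code{init_state}.
#' @examples
#' m <- generate_msequence(11)
#' length(m$bits)  # 2047
#' sum(m$bits)     # 1024
#' @export
generate_msequence <- function(degree, taps = NULL, init_state = NULL) {
  if (!is.numeric(degree) || length(degree) != 1L || degree < 2 || degree != round(degree))
    stop("`degree` must be a single integer >= 2")
  degree <- as.integer(degree)
  if (is.null(taps)) taps <- default_taps(degree)
  taps <- sort(unique(as.integer(taps)), decreasing = TRUE)
  if (any(taps < 1L) || any(taps > degree) || !(degree %in% taps))
    stop("`taps` must be positions in 1:degree and include `degree` itself")
  if (is.null(init_state)) init_state <- c(1L, integer(degree - 1L))
  init_state <- as.integer(init_state)
  if (length(init_state) != degree || any(!init_state %in% c(0L, 1L)))
    stop("`init_state` must be a 0/1 vector of length `degree`")
  if (all(init_state == 0L)) stop("`init_state` must be nonzero")

  period <- 2L^degree - 1L
  state <- init_state
  pow2 <- 2^(seq_len(degree) - 1)
  code0 <- sum(state * pow2)
  bits <- integer(period)
  for (i in seq_len(period)) {
    bits[i] <- state[degree]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-degree])
    if (i < period && sum(state * pow2) == code0)
      stop(sprintf(
        "taps do not form a primitive polynomial: observed period %d < %d",
        i, period))
  }
  if (sum(state * pow2) != code0)
    stop(sprintf(
      "taps do not form a primitive polynomial: state did not recur at period %d",
      period))
  structure(list(bits = bits, degree = degree, taps = taps,
                 init_state = init_state),
            class = "msequence")
}

# Known primitive feedback tap sets (Fibonacci convention) per degree.
default_taps <- function(degree) {
  tab <- list(`2` = c(2, 1), `3` = c(3, 2), `4` = c(4, 3), `5` = c(5, 3),
              `6` = c(6, 5), `7` = c(7, 6), `8` = c(8, 6, 5, 4),
              `9` = c(9, 5), `10` = c(10, 7), `11` = c(11, 9),
              `12` = c(12, 11, 10, 4), `13` = c(13, 12, 11, 8),
              `14` = c(14, 13, 12, 2), `15` = c(15, 14), `16` = c(16, 15, 13, 4))
  key <- as.character(degree)
  if (is.null(tab[[key]]))
    stop("no default taps stored for degree ", degree, "; supply `taps`")
  as.integer(tab[[key]])
}

#' Find distinct primitive tap sets by seeded search
#'
#' Randomly samples feedback tap sets of the given degree and keeps those
#' whose LFSR achieves the full period \eqn{2^k - 1}. Used to obtain the
#' distinct m-sequences that successive stimulation repetitions are built
#' from.
#'
#' @param degree LFSR degree.
#' @param n Number of distinct primitive tap sets required.
#' @param seed Integer seed driving the random search.
#' @param max_tries Upper bound on candidate draws before giving up.
#' @return A list of `n` integer tap vectors.
#' @export
find_primitive_taps <- function(degree, n, seed = 1L, max_tries = 5000L) {
  stopifnot(degree >= 2, n >= 1)
  found <- list()
  keys <- character(0)
  rng <- local({ set.seed(as.integer(seed)); NULL })
  set.seed(as.integer(seed))
  tries <- 0L
  while (length(found) < n && tries < max_tries) {
    tries <- tries + 1L
    k <- sample(c(1L, 3L), 1L)  # 2 or 4 taps total incl. degree -> even weight
    others <- sort(sample(seq_len(degree - 1L), k))
    taps <- sort(unique(c(degree, others)), decreasing = TRUE)
    key <- paste(taps, collapse = ",")
    if (key %in% keys) next
    ok <- tryCatch({ generate_msequence(degree, taps); TRUE },
                   error = function(e) FALSE)
    if (ok) {
      found[[length(found) + 1L]] <- taps
      keys <- c(keys, key)
    }
  }
  if (length(found) < n)
    stop("found only ", length(found), " primitive tap sets after ",
         tries, " tries")
  found
}

#' Rotate a periodic binary sequence to start at a run boundary
#'
#' Cyclically rotates `bits` so that the first element is the start of a run
#' of ones (its cyclic predecessor is 0). Thinning a full period rotated this
#' way removes the ambiguity of a ones-run wrapping around the period edge,
#' making the retained pulse count exactly half the number of ones runs.
#'
#' @param bits 0/1 vector (one period).
#' @return The rotated vector, with attribute `"rotation"` giving the offset
#'   such that `result[i] == bits[((i - 1 + rotation) %% length(bits)) + 1]`.
#' @export
rotate_to_run_boundary <- function(bits) {
  bits <- as.integer(bits)
  n <- length(bits)
  if (n == 0L || all(bits == 0L) || all(bits == 1L))
    return(structure(bits, rotation = 0L))
  prev <- c(bits[n], bits[-n])
  starts <- which(bits == 1L & prev == 0L)
  k <- starts[1L]
  rot <- k - 1L
  out <- if (rot == 0L) bits else c(bits[(rot + 1L):n], bits[1:rot])
  structure(out, rotation = rot)
}

#' Two-pass pulse thinning
#'
#' Reduces the pulse density of a binary event stream in two passes:
#' pass 1 keeps only the first 1 of every run of consecutive 1s; pass 2 keeps
#' the 1st, 3rd, 5th, ... of the surviving pulses in temporal order.
#' Applied to one full period of a degree-11 m-sequence rotated to a run
#' boundary (see [rotate_to_run_boundary()]), this retains 256 of the
#' original 1024 pulses. The scan is linear; rotate the period first if the
#' cyclic run structure should be respected.
#'
#' @param bits 0/1 vector.
#' @return 0/1 integer vector of the same length.
#' @examples
#' thin_pulse_stream(c(1, 1, 0, 1, 0, 1))  # 1 0 0 0 0 1
#' @export
thin_pulse_stream <- function(bits) {
  bits <- as.integer(bits)
  if (any(!bits %in% c(0L, 1L))) stop("`bits` must be 0/1")
  n <- length(bits)
  if (n == 0L || !any(bits == 1L)) return(bits)
  # pass 1: keep run starts only
  prev <- c(0L, bits[-n])
  pass1 <- as.integer(bits == 1L & prev == 0L)
  # pass 2: odd-ranked survivors
  surv <- which(pass1 == 1L)
  keep <- surv[seq(1L, length(surv), by = 2L)]
  out <- integer(n)
  out[keep] <- 1L
  out
}

#' Build a multi-location time-lagged pulse train
#'
#' Constructs the stimulation event matrix for `n_locations` visual-field
#' locations: every row is the same (thinned) base sequence cyclically
#' shifted by a location-specific lag, so that all locations share identical
#' event statistics while their streams stay mutually uncorrelated.
#' Repetitions concatenate periods built from distinct base sequences.
#'
#' @param thinned A 0/1 vector (one period) or a list of such vectors, one
#'   per repetition. A single vector with `n_repetitions > 1` is reused for
#'   every repetition.
#' @param n_locations Number of stimulus locations (rows).
#' @param lag_spacing Cyclic shift between consecutive rows, in frames.
#'   Defaults to `floor(period / n_locations)`.
#' @param n_repetitions Number of concatenated periods.
#' @param frame_rate Stimulation frame rate in Hz (frames per second).
#' @param meta Optional list of metadata (e.g. seed) stored with the train.
#' @return An object of class \code{"pulse_train"}: a list with `events`
#'   (n_locations x n_frames 0/1 matrix), `frame_rate`, `lags`, `period`
#'   (frames per repetition), `n_repetitions` and `meta`.
#' @export
build_pulse_train <- function(thinned, n_locations, lag_spacing = NULL,
                              n_repetitions = 1L, frame_rate = 40,
                              meta = list()) {
  if (!is.list(thinned)) {
    thinned <- rep(list(as.integer(thinned)), n_repetitions)
  } else if (length(thinned) != n_repetitions) {
    stop("`thinned` list length must equal `n_repetitions`")
  }
  period <- length(thinned[[1L]])
  if (any(vapply(thinned, length, 1L) != period))
    stop("all repetition sequences must share the same period length")
  if (is.null(lag_spacing)) lag_spacing <- period %/% n_locations
  if (n_locations * lag_spacing > period && n_locations > 1L)
    stop("n_locations * lag_spacing exceeds the period length")
  lags <- (seq_len(n_locations) - 1L) * as.integer(lag_spacing)

  one_rep <- function(bits) {
    t(vapply(lags, function(l) {
      if (l == 0L) bits else c(bits[(l + 1L):period], bits[seq_len(l)])
    }, integer(period)))
  }
  blocks <- lapply(thinned, one_rep)
  events <- do.call(cbind, blocks)
  if (n_locations > 1L) {
    first <- blocks[[1L]]
    if (anyDuplicated(apply(first, 1L, paste, collapse = "")))
      stop("lag collision: two locations received identical pulse streams")
  }
  structure(list(events = events, frame_rate = frame_rate, lags = lags,
                 period = period, n_repetitions = as.integer(n_repetitions),
                 meta = meta),
            class = "pulse_train")
}

#' Design a complete thinned multi-location pulse train
#'
#' End-to-end stimulus design: finds `n_repetitions` distinct primitive
#' polynomials of the given degree (seeded search), generates one m-sequence
#' period from each, rotates every period to a run boundary, applies the
#' two-pass thinning, and assembles the time-lagged multi-location train.
#' With the defaults (degree 11, 16 locations, 10 repetitions, 40 frames/s)
#' this reproduces the standard multifocal design: 256 pulses per location
#' per 2047-frame period, 2560 events per location in total, a mean
#' per-location event rate near 5 Hz and an overall any-location event rate
#' near 35 Hz.
#'
#' @param degree m-sequence degree (default 11, period 2047).
#' @param n_locations Number of stimulus locations (default 16).
#' @param n_repetitions Number of repetitions, each from a distinct
#'   m-sequence (default 10).
#' @param lag_spacing Cyclic lag between locations in frames; default
#'   `floor(period / n_locations)`.
#' @param frame_rate Frames per second (default 40).
#' @param seed Integer seed for the primitive-polynomial search.
#' @return A [build_pulse_train()] object; `meta` records the seed and the
#'   tap sets used.
#' @export
design_pulse_train <- function(degree = 11L, n_locations = 16L,
                               n_repetitions = 10L, lag_spacing = NULL,
                               frame_rate = 40, seed = 1L) {
  taps <- find_primitive_taps(degree, n_repetitions, seed = seed)
  periods <- lapply(taps, function(tp) {
    thin_pulse_stream(rotate_to_run_boundary(generate_msequence(degree, tp)$bits))
  })
  build_pulse_train(periods, n_locations = n_locations,
                    lag_spacing = lag_spacing, n_repetitions = n_repetitions,
                    frame_rate = frame_rate,
                    meta = list(seed = as.integer(seed), degree = degree,
                                taps = taps))
}

#' Event-rate summary of a pulse train
#'
#' @param train A `pulse_train`.
#' @return A list with `per_location_hz` (mean events per second per
#'   location) and `any_location_hz` (rate of frames containing at least one
#'   event across all locations).
#' @export
event_rates <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  n_frames <- ncol(train$events)
  dur <- n_frames / train$frame_rate
  list(per_location_hz = mean(rowSums(train$events)) / dur,
       any_location_hz = sum(colSums(train$events) > 0) / dur)
}

#' Stream-pair autocorrelation diagnostics
#'
#' Pearson correlation between every pair of pulse streams at cyclic lags
#' 0..`max_lag`. Diagonal pairs give the within-stream autocorrelation
#' (structured at small lags because thinning forbids consecutive pulses);
#' off-diagonal pairs should stay at chance level at every lag — the design
#' property that keeps per-location waveform estimates unconfounded.
#'
#' @param train A `pulse_train`.
#' @param max_lag Largest cyclic lag in frames; must be below the period.
#' @return Numeric array of dim `(n_locations, n_locations, max_lag + 1)`;
#'   entry `[i, j, l]` is `cor(row_i, rotate(row_j, lag = l - 1))`.
#' @export
autocorrelation_matrix <- function(train, max_lag) {
  stopifnot(inherits(train, "pulse_train"))
  ev <- train$events
  n <- ncol(ev)
  if (max_lag >= train$period) stop("`max_lag` must be below the period length")
  nl <- nrow(ev)
  out <- array(NA_real_, dim = c(nl, nl, max_lag + 1L))
  evt <- t(ev)
  for (l in 0:max_lag) {
    shifted <- if (l == 0L) evt else evt[c((l + 1L):n, seq_len(l)), , drop = FALSE]
    out[, , l + 1L] <- stats::cor(evt, shifted)
  }
  dimnames(out) <- list(NULL, NULL, paste0("lag", 0:max_lag))
  out
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> %d locations x %d frames (%d reps of %d) at %g frames/s\n",
    nrow(x$events), ncol(x$events), x$n_repetitions, x$period, x$frame_rate))
  r <- event_rates(x)
  cat(sprintf("  events/location: %d;  per-location rate %.2f Hz;  any-location rate %.2f Hz\n",
              sum(x$events[1L, ]), r$per_location_hz, r$any_location_hz))
  invisible(x)
}

#' Write / read a pulse train as plain text
#'
#' One header block of `# key: value` lines followed by one row of 0/1
#' characters per location.
#'
#' @param train A `pulse_train`.
#' @param path File path.
#' @rdname pulse_train_io
#' @export
write_pulse_train <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  hdr <- c(sprintf("# frame_rate: %.10g", train$frame_rate),
           sprintf("# period: %d", train$period),
           sprintf("# n_repetitions: %d", train$n_repetitions),
           sprintf("# lags: %s", paste(train$lags, collapse = ",")))
  rows <- apply(train$events, 1L, paste, collapse = "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname pulse_train_io
#' @export
read_pulse_train <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get <- function(key) sub(sprintf("^# %s: ", key), "", hdr[grepl(paste0("^# ", key, ":"), hdr)])
  rows <- lines[!is_hdr]
  ev <- t(vapply(rows, function(s) as.integer(strsplit(s, "")[[1L]]),
                 integer(nchar(rows[1L]))))
  dimnames(ev) <- NULL
  structure(list(events = ev,
                 frame_rate = as.numeric(get("frame_rate")),
                 lags = as.integer(strsplit(get("lags"), ",")[[1L]]),
                 period = as.integer(get("period")),
                 n_repetitions = as.integer(get("n_repetitions")),
                 meta = list()),
            class = "pulse_train")
}
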