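# Global field power, SNR summaries, cross-temporal topographic correlation,
# component detection and component/area correlation analytics.

#' Global field power of an mVEP estimate
#'
#' GFP at a time point is the spatial standard deviation of the
#' average-referenced field across channels (Lehmann–Skrandies), computed per
#' stimulus location and optionally averaged across locations.
#'
#' @param mvep An `mvep_estimate`.
#' @param per_location If `TRUE`, return the locations x time matrix; else
#'   the across-location mean time course.
#' @return Object of class \code{"gfp_timecourse"}: `values` (vector or
#'   matrix), `times_ms`, `per_location`.
#' @export
gfp <- function(mvep, per_location = FALSE) {
  stopifnot(inherits(mvep, "mvep_estimate"))
  W <- mvep$waveforms
  n_ch <- dim(W)[1]
  # population spatial SD per (location, time)
  mu <- apply(W, c(2, 3), mean)
  g <- sqrt(apply(W^2, c(2, 3), mean) - mu^2)
  if (!per_location) g <- colMeans(g)
  structure(list(values = g, times_ms = mvep$epoch$times_ms,
                 per_location = per_location, condition = mvep$condition),
            class = "gfp_timecourse")
}

window_mean <- function(values, times_ms, window) {
  sel <- times_ms >= window[1] & times_ms <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] ms lies outside the epoch")
  if (is.matrix(values)) rowMeans(values[, sel, drop = FALSE])
  else mean(values[sel])
}

#' Signal-to-noise summary between two conditions
#'
#' Compares the across-location mean GFP of two mVEPs in a signal window
#' and a pre-stimulus baseline window: the between-condition GFP ratio in
#' each window, the within-condition SNR (signal / baseline), and the
#' between-condition SNR ratio.
#'
#' @param mvep_a,mvep_b `mvep_estimate` objects (e.g. pulse and reversal).
#' @param signal_window Signal window in ms (default 80--90).
#' @param baseline_window Baseline window in ms (default -50--0).
#' @return List with `signal_gfp`, `baseline_gfp` (per condition),
#'   `signal_ratio`, `baseline_ratio`, `snr` (per condition), `snr_ratio`.
#' @export
snr_summary <- function(mvep_a, mvep_b, signal_window = c(80, 90),
                        baseline_window = c(-50, 0)) {
  ga <- gfp(mvep_a); gb <- gfp(mvep_b)
  sa <- window_mean(ga$values, ga$times_ms, signal_window)
  sb <- window_mean(gb$values, gb$times_ms, signal_window)
  ba <- window_mean(ga$values, ga$times_ms, baseline_window)
  bb <- window_mean(gb$values, gb$times_ms, baseline_window)
  eps <- 1e-12 * max(sa, sb)
  if (ba <= eps || bb <= eps)
    stop("baseline GFP is (near) zero; SNR is undefined for noiseless input")
  list(signal_gfp = c(a = sa, b = sb),
       baseline_gfp = c(a = ba, b = bb),
       signal_ratio = sa / sb,
       baseline_ratio = ba / bb,
       snr = c(a = sa / ba, b = sb / bb),
       snr_ratio = (sa / ba) / (sb / bb))
}

# channels x locations x time -> (channels*locations) x time, channel
# varying fastest within each location (matches stack_regressor())
stack_waveforms <- function(W) {
  d <- dim(W)
  matrix(W, d[1] * d[2], d[3])
}

#' Cross-temporal topographic correlation matrix
#'
#' At every time point the waveforms over all channels and locations are
#' stacked into one vector; the matrix holds the Pearson correlation between
#' these vectors for every pair of time points. Time points with zero
#' spatial variance yield missing values (reported via a message).
#'
#' @param mvep An `mvep_estimate`.
#' @return time x time symmetric correlation matrix with unit diagonal.
#' @export
topographic_crosscorrelation <- function(mvep) {
  stopifnot(inherits(mvep, "mvep_estimate"))
  S <- stack_waveforms(mvep$waveforms)
  sds <- apply(S, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    message(sum(zero), " time point(s) have zero spatial variance; ",
            "correlations set to NA")
  cc <- suppressWarnings(stats::cor(S))
  cc[zero, ] <- NA_real_
  cc[, zero] <- NA_real_
  diag(cc)[!zero] <- 1
  dimnames(cc) <- list(NULL, NULL)
  cc
}

# peak prominence: height above the higher of the two minima separating the
# peak from the nearest higher point on each side (or the series edge)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    higher_l <- which(y[seq_len(p - 1)] > y[p])
    lo <- if (length(higher_l)) max(higher_l) else 1L
    base_l <- min(y[lo:p])
    higher_r <- which(y[(p + 1):length(y)] > y[p]) + p
    hi <- if (length(higher_r)) min(higher_r) else length(y)
    base_r <- min(y[p:hi])
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Detect mVEP components from a GFP time course
#'
#' Finds the `n_peaks` most prominent local maxima of the across-location
#' GFP inside the search window, orders them by latency (C1, C2, ...), and
#' attaches a +/- `half_window_ms` averaging window to each. Also returns
#' the GFP-dip latencies (minima between consecutive peaks), used by the
#' component-transition tests.
#'
#' @param g A `gfp_timecourse` averaged across locations.
#' @param n_peaks Number of components (default 3).
#' @param search_window Latency window in ms to search (default 50--300).
#' @param half_window_ms Half width of the component averaging window
#'   (default 5, i.e. 10-ms windows).
#' @return Object of class \code{"component_set"}: `labels`, `latencies_ms`,
#'   `windows` (n x 2), `dips_ms`, `ties` flag.
#' @export
find_components <- function(g, n_peaks = 3L, search_window = c(50, 300),
                            half_window_ms = 5) {
  stopifnot(inherits(g, "gfp_timecourse"))
  if (g$per_location) stop("use the across-location mean GFP")
  y <- g$values
  t_ms <- g$times_ms
  in_win <- which(t_ms >= search_window[1] & t_ms <= search_window[2])
  cand <- in_win[in_win > 1 & in_win < length(y)]
  is_peak <- cand[y[cand] > y[cand - 1] & y[cand] >= y[cand + 1]]
  if (length(is_peak) < n_peaks)
    stop("found only ", length(is_peak), " local maxima (",
         paste(round(t_ms[is_peak], 1), collapse = ", "),
         " ms) in the search window; need ", n_peaks)
  prom <- peak_prominence(y, is_peak)
  ord <- order(-prom, t_ms[is_peak])     # prominence, ties by earlier latency
  sel <- sort(is_peak[ord[seq_len(n_peaks)]])
  ties <- anyDuplicated(signif(prom, 12)) > 0
  lat <- t_ms[sel]
  windows <- cbind(lat - half_window_ms, lat + half_window_ms)
  dips <- vapply(seq_len(n_peaks - 1L), function(i) {
    seg <- sel[i]:sel[i + 1L]
    t_ms[seg[which.min(y[seg])]]
  }, numeric(1))
  structure(list(labels = paste0("C", seq_len(n_peaks)),
                 latencies_ms = lat, windows = windows, dips_ms = dips,
                 ties = ties, condition = g$condition),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %s: %s at %s ms (dips %s ms)\n",
              x$condition, paste(x$labels, collapse = "/"),
              paste(round(x$latencies_ms, 1), collapse = "/"),
              paste(round(x$dips_ms, 1), collapse = "/")))
  invisible(x)
}

#' Window-averaged component topographies
#'
#' @param mvep An `mvep_estimate`.
#' @param windows n x 2 matrix of ms windows (or a `component_set`).
#' @return channels x locations x n array of window-averaged fields.
#' @export
component_topographies <- function(mvep, windows) {
  if (inherits(windows, "component_set")) windows <- windows$windows
  windows <- rbind(windows)
  t_ms <- mvep$epoch$times_ms
  out <- array(NA_real_, dim = c(dim(mvep$waveforms)[1:2], nrow(windows)))
  for (i in seq_len(nrow(windows))) {
    sel <- t_ms >= windows[i, 1] & t_ms <= windows[i, 2]
    if (!any(sel)) stop("component window outside the epoch")
    out[, , i] <- apply(mvep$waveforms[, , sel, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Component-pair correlation table across two conditions
#'
#' Every component is represented by its window-averaged field stacked over
#' all channels and locations (the retinotopic pattern of topography); the
#' table holds all pairwise Pearson correlations within and between the two
#' conditions.
#'
#' @param comp_a,comp_b `component_set`s of the two conditions.
#' @param mvep_a,mvep_b The matching `mvep_estimate`s.
#' @return 6 x 6 (or 2 n_peaks square) correlation matrix with labelled rows.
#' @export
component_pair_correlations <- function(comp_a, mvep_a, comp_b, mvep_b) {
  Ta <- component_topographies(mvep_a, comp_a)
  Tb <- component_topographies(mvep_b, comp_b)
  va <- apply(Ta, 3, as.vector)
  vb <- apply(Tb, 3, as.vector)
  M <- cbind(va, vb)
  colnames(M) <- c(paste0(mvep_a$condition, ".", comp_a$labels),
                   paste0(mvep_b$condition, ".", comp_b$labels))
  stats::cor(M)
}

#' Dip-component correlation test across participants
#'
#' For each participant and condition, correlates the topographic pattern at
#' the GFP dip with the pattern of a reference component (both stacked over
#' channels and locations, window-averaged). Group inference is on
#' Fisher-z-transformed correlations: a one-sample test against zero per
#' condition and a paired between-condition comparison, both reported as
#' F(1, n-1) = t^2 with two-sided p.
#'
#' @param mveps_a,mveps_b Lists of per-participant `mvep_estimate`s (same
#'   participants, two conditions).
#' @param dip_ms_a,dip_ms_b Dip latency (ms) per condition.
#' @param comp_window_a,comp_window_b Component window (ms, length 2) per
#'   condition.
#' @param half_window_ms Half width of the dip averaging window.
#' @return List with `r` (participants x 2 matrix), `group` (per-condition
#'   mean r, F, p), `paired` (F, p, df).
#' @export
dip_correlation_test <- function(mveps_a, mveps_b, dip_ms_a, dip_ms_b,
                                 comp_window_a, comp_window_b,
                                 half_window_ms = 5) {
  n <- length(mveps_a)
  if (n < 2L || length(mveps_b) != n)
    stop("need the same >= 2 participants in both conditions")
  one_r <- function(mvep, dip_ms, comp_window) {
    tops <- component_topographies(
      mvep, rbind(c(dip_ms - half_window_ms, dip_ms + half_window_ms),
                  comp_window))
    stats::cor(as.vector(tops[, , 1]), as.vector(tops[, , 2]))
  }
  r <- cbind(a = vapply(mveps_a, one_r, numeric(1), dip_ms_a, comp_window_a),
             b = vapply(mveps_b, one_r, numeric(1), dip_ms_b, comp_window_b))
  z <- atanh(pmin(pmax(r, -0.999999), 0.999999))
  one_sample <- function(zc) {
    if (stats::sd(zc) < 1e-12 * max(1, abs(mean(zc)))) {
      # degenerate: no variability across participants
      return(c(F = if (abs(mean(zc)) > 0) Inf else 0,
               p = if (abs(mean(zc)) > 0) 0 else 1))
    }
    tt <- stats::t.test(zc)
    c(F = unname(tt$statistic)^2, p = tt$p.value)
  }
  ga <- one_sample(z[, 1]); gb <- one_sample(z[, 2])
  pd <- one_sample(z[, 1] - z[, 2])
  list(r = r,
       group = data.frame(condition = c("a", "b"),
                          mean_r = c(mean(r[, 1]), mean(r[, 2])),
                          F = c(ga["F"], gb["F"]),
                          p = c(ga["p"], gb["p"]),
                          df1 = 1, df2 = n - 1),
       paired = list(F = unname(pd["F"]), p = unname(pd["p"]),
                     df = c(1, n - 1)))
}

#' Component x visual-area x location correlations
#'
#' Correlates every component's 128-channel topography at each stimulus
#' location with each visual area's predicted topography for that location.
#' The area with the largest absolute location-averaged correlation is
#' flagged per component, with the sign of that average retained.
#'
#' @param topo channels x locations x components array (from
#'   [component_topographies()]), or a list of such arrays to be
#'   concatenated along the component axis.
#' @param predictions A `prediction_matrix`.
#' @param component_labels Optional component names.
#' @return List with `r` (areas x components x locations array),
#'   `mean_r` (areas x components), `best_area` (named character vector),
#'   `sign_consistent` (areas x components: does r keep one sign across all
#'   locations?).
#' @export
area_component_location_correlations <- function(topo, predictions,
                                                 component_labels = NULL) {
  if (is.list(topo)) topo <- do.call(function(...) abind3(...), topo)
  d <- dim(topo)
  areas <- predictions$area_names
  n_loc <- d[2]
  n_comp <- d[3]
  if (is.null(component_labels)) component_labels <- paste0("comp", seq_len(n_comp))
  r <- array(NA_real_, dim = c(length(areas), n_comp, n_loc),
             dimnames = list(areas, component_labels, NULL))
  for (a in seq_along(areas)) for (k in seq_len(n_comp)) for (l in seq_len(n_loc))
    r[a, k, l] <- stats::cor(topo[, l, k], predictions$values[areas[a], l, ])
  mean_r <- apply(r, c(1, 2), mean)
  best <- component_labels
  best_area <- vapply(seq_len(n_comp), function(k)
    areas[which.max(abs(mean_r[, k]))], character(1))
  names(best_area) <- component_labels
  sign_consistent <- apply(r, c(1, 2), function(v)
    all(v > 0) || all(v < 0))
  list(r = r, mean_r = mean_r, best_area = best_area,
       sign_consistent = sign_consistent)
}

# minimal 3rd-axis array bind (avoids an abind dependency)
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:2]
  n3 <- sum(vapply(xs, function(x) dim(x)[3], numeric(1)))
  out <- array(NA_real_, dim = c(d, n3))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[3]
    out[, , at + seq_len(k)] <- x
    at <- at + k
  }
  out
}
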