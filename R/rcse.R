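# Retinotopically constrained source regression: z-scored stacked
# regressors, sliding-window single-area and full-model fits, forward
# selection by BIC, and participant bootstrap for beta standard errors.

#' Sliding-window grid over the epoch
#'
#' Half-open windows `[t, t + width)` ms with uniform step.
#'
#' @param width_ms Window width (default 10 ms).
#' @param step_ms Step between window starts (default 5 ms).
#' @param span_ms Epoch span (default -100..400 ms), giving 99 windows at
#'   the defaults.
#' @return Object of class \code{"window_grid"} with `starts_ms`,
#'   `centers_ms`, `width_ms`.
#' @export
window_grid <- function(width_ms = 10, step_ms = 5, span_ms = c(-100, 400)) {
  starts <- seq(span_ms[1], span_ms[2] - width_ms, by = step_ms)
  structure(list(starts_ms = starts, centers_ms = starts + width_ms / 2,
                 width_ms = width_ms, step_ms = step_ms, span_ms = span_ms),
            class = "window_grid")
}

# 0/1-normalized averaging matrix (epoch samples x windows)
window_average_matrix <- function(times_ms, wg) {
  A <- vapply(wg$starts_ms, function(s) {
    sel <- times_ms >= s & times_ms < s + wg$width_ms
    if (!any(sel)) stop("empty window at ", s, " ms")
    sel / sum(sel)
  }, numeric(length(times_ms)))
  A
}

#' Standardize stacked responses and area regressors
#'
#' Stacks the mVEP waveforms over channels and locations (2048 elements for
#' 128 channels x 16 locations), averages them inside each sliding window,
#' and converts them to z-scores using the mean and SD of the stacked mVEP
#' over the full epoch (one shared pair of moments for every window). Each
#' area regressor is standardized by its own mean and SD over its elements.
#'
#' @param mvep An `mvep_estimate` (typically the grand average).
#' @param predictions A `prediction_matrix` covering the areas to model.
#' @param windows A [window_grid()].
#' @return List with `responses` (elements x windows), `regressors`
#'   (elements x areas), `centers_ms`, `mvep_moments` (mean, sd used).
#' @export
zscore_stack <- function(mvep, predictions, windows = window_grid()) {
  S <- stack_waveforms(mvep$waveforms)
  n_el <- nrow(S)
  if (n_el != dim(predictions$values)[2] * dim(predictions$values)[3])
    stop("mvep and prediction dimensions are inconsistent")
  mu <- mean(S); sd_full <- stats::sd(as.vector(S))
  if (sd_full == 0) stop("mVEP has zero variance over the epoch")
  A <- window_average_matrix(mvep$epoch$times_ms, windows)
  R <- (S %*% A - mu) / sd_full
  regs <- vapply(predictions$area_names, function(a) {
    v <- stack_regressor(predictions, a)
    s <- stats::sd(v)
    if (s == 0) stop("zero-SD regressor for area ", a)
    (v - mean(v)) / s
  }, numeric(n_el))
  list(responses = R, regressors = regs, centers_ms = windows$centers_ms,
       mvep_moments = c(mean = mu, sd = sd_full))
}

#' Single-area sliding-window fits
#'
#' Per window, OLS of the standardized response on one standardized area
#' regressor (with intercept); reports R-squared.
#'
#' @param responses elements x windows matrix (from [zscore_stack()]).
#' @param regressor One standardized regressor (elements).
#' @return Numeric vector of per-window R-squared values.
#' @export
single_area_fit <- function(responses, regressor) {
  if (stats::sd(regressor) == 0) stop("degenerate regressor")
  as.numeric(stats::cor(regressor, responses))^2
}

#' Full-model sliding-window fits
#'
#' Per window, multiple OLS of the standardized response on all area
#' regressors plus an intercept. Refuses ill-conditioned designs rather
#' than regularizing, since the source model relies on plain regression.
#'
#' @param responses elements x windows matrix.
#' @param regressors elements x areas matrix of standardized regressors.
#' @param condition_ceiling Maximum design condition number (default 1e6).
#' @return List with `betas` (areas x windows), `r2` (windows),
#'   `residual_ss` (windows).
#' @export
full_model_fit <- function(responses, regressors,
                           condition_ceiling = 1e6) {
  X <- cbind(`(intercept)` = 1, regressors)
  kap <- kappa(X, exact = TRUE)
  if (kap > condition_ceiling) {
    warning("design condition number ", format(kap, digits = 3),
            " exceeds the ceiling")
    stop("near-collinear area regressors; refusing to fit")
  }
  qx <- qr(X)
  B <- qr.coef(qx, responses)
  fitted <- X %*% B
  rss <- colSums((responses - fitted)^2)
  tss <- colSums(sweep(responses, 2, colMeans(responses))^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  list(betas = B[-1, , drop = FALSE], intercepts = B[1, ], r2 = r2,
       residual_ss = rss)
}

#' Forward-selection BIC path over area regressors
#'
#' Greedy forward selection: starting from the intercept-only model, at each
#' step the area whose addition minimizes
#' \eqn{BIC = n \log(RSS/n) + k \log(n)} (k counting all coefficients
#' including the intercept) joins the model; the path is recorded for all
#' steps up to the full set of areas, and the BIC-optimal prefix is flagged.
#'
#' @param response One standardized response vector (e.g. the 80--90 ms
#'   window).
#' @param regressors elements x areas matrix.
#' @return data.frame with `step`, `area`, `bic`, `r2`, `selected`
#'   (TRUE within the BIC-optimal prefix).
#' @export
stepwise_bic <- function(response, regressors) {
  n <- length(response)
  areas <- colnames(regressors)
  if (is.null(areas)) areas <- paste0("A", seq_len(ncol(regressors)))
  chosen <- integer(0)
  path <- data.frame(step = integer(0), area = character(0),
                     bic = numeric(0), r2 = numeric(0))
  tss <- sum((response - mean(response))^2)
  for (step in seq_len(ncol(regressors))) {
    cand <- setdiff(seq_len(ncol(regressors)), chosen)
    bics <- vapply(cand, function(j) {
      X <- cbind(1, regressors[, c(chosen, j), drop = FALSE])
      rss <- sum(qr.resid(qr(X), response)^2)
      n * log(rss / n) + (ncol(X)) * log(n)
    }, numeric(1))
    best <- cand[which.min(bics)]
    chosen <- c(chosen, best)
    X <- cbind(1, regressors[, chosen, drop = FALSE])
    rss <- sum(qr.resid(qr(X), response)^2)
    path <- rbind(path, data.frame(
      step = step, area = areas[best], bic = min(bics),
      r2 = 1 - rss / tss))
  }
  path$selected <- seq_len(nrow(path)) <= which.min(path$bic)
  path
}

#' Participant bootstrap of full-model beta standard errors
#'
#' Resamples participants with replacement, recomputes the grand average and
#' the full-model betas per window for each replicate, and reports the SD of
#' each beta over replicates as its standard error.
#'
#' @param mveps List of per-participant `mvep_estimate`s.
#' @param predictions A `prediction_matrix`.
#' @param windows A [window_grid()].
#' @param n_boot Number of bootstrap replicates (study value 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @return areas x windows matrix of bootstrap standard errors.
#' @export
bootstrap_beta_se <- function(mveps, predictions, windows = window_grid(),
                              n_boot = 1000L, seed = 1L) {
  n <- length(mveps)
  if (n < 2L) stop("need at least 2 participants to bootstrap")
  set.seed(as.integer(seed))
  stacks <- lapply(mveps, function(m) stack_waveforms(m$waveforms))
  A <- window_average_matrix(mveps[[1]]$epoch$times_ms, windows)
  regs <- zscore_stack(mveps[[1]], predictions, windows)$regressors
  X <- cbind(1, regs)
  qx <- qr(X)
  n_area <- ncol(regs)
  out <- array(NA_real_, dim = c(n_area, ncol(A), n_boot))
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n, n, replace = TRUE)
    S <- Reduce(`+`, stacks[pick]) / n
    mu <- mean(S); sdv <- stats::sd(as.vector(S))
    R <- (S %*% A - mu) / sdv
    B <- qr.coef(qx, R)
    out[, , b] <- B[-1, , drop = FALSE]
  }
  se <- apply(out, c(1, 2), stats::sd)
  dimnames(se) <- list(colnames(regs), NULL)
  se
}

#' Complete retinotopically constrained source regression
#'
#' Convenience wrapper running [zscore_stack()], per-area
#' [single_area_fit()]s, the [full_model_fit()], and the [stepwise_bic()]
#' path anchored on the 80--90 ms response window.
#'
#' @param mvep Grand-average `mvep_estimate`.
#' @param predictions A `prediction_matrix`.
#' @param windows A [window_grid()].
#' @param stepwise_window_ms Window (start ms) anchoring the stepwise
#'   selection (default 80, i.e. the 80--90 ms window).
#' @return Object of class \code{"rcse_result"}: `single_area_r2` (areas x
#'   windows), `full_betas`, `full_r2`, `bic_path`, `centers_ms`,
#'   `mvep_moments`.
#' @export
rcse_fit <- function(mvep, predictions, windows = window_grid(),
                     stepwise_window_ms = 80) {
  zs <- zscore_stack(mvep, predictions, windows)
  single <- t(vapply(seq_len(ncol(zs$regressors)), function(j)
    single_area_fit(zs$responses, zs$regressors[, j]),
    numeric(ncol(zs$responses))))
  rownames(single) <- colnames(zs$regressors)
  full <- full_model_fit(zs$responses, zs$regressors)
  wi <- which.min(abs(windows$starts_ms - stepwise_window_ms))
  path <- stepwise_bic(zs$responses[, wi], zs$regressors)
  structure(list(single_area_r2 = single, full_betas = full$betas,
                 full_r2 = full$r2, bic_path = path,
                 centers_ms = zs$centers_ms,
                 stepwise_window_start_ms = windows$starts_ms[wi],
                 mvep_moments = zs$mvep_moments),
            class = "rcse_result")
}

#' @export
print.rcse_result <- function(x, ...) {
  best <- rownames(x$single_area_r2)[apply(x$single_area_r2, 2, which.max)]
  peak <- which.max(x$full_r2)
  cat(sprintf(
    "<rcse_result> %d areas x %d windows; full-model R2 peaks at %.2f (%g ms); first selected area: %s\n",
    nrow(x$single_area_r2), ncol(x$single_area_r2),
    x$full_r2[peak], x$centers_ms[peak], x$bic_path$area[1]))
  invisible(x)
}
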