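#' Delay grids for information transfer analysis
#'
#' Within- and between-lead information transfer constants are computed on
#' a grid of positive integer sample lags.  The default within-lead grid is
#' `{1, 2, 4, 8, 16}` samples (4-64 ms at 250 Hz); the default between-lead
#' grid is 5 lags log-spaced from 1 sample to 1000 samples (4 ms to 4 s at
#' 250 Hz), i.e. `{1, 6, 32, 178, 1000}`.  Both are fully configurable.
#'
#' @param n_delays,min_lag,max_lag between-lead grid shape: `n_delays`
#'   integer lags log-spaced over `[min_lag, max_lag]` samples.
#' @return Integer vector of sample lags, strictly increasing.
#' @export
itm_within_grid <- function() c(1L, 2L, 4L, 8L, 16L)

#' @rdname itm_within_grid
#' @export
itm_between_grid <- function(n_delays = 5L, min_lag = 1L, max_lag = 1000L) {
  stopifnot(n_delays >= 1L, min_lag >= 1L, max_lag > min_lag)
  unique(as.integer(round(exp(seq(log(min_lag), log(max_lag), length.out = n_delays)))))
}

check_delays <- function(delays, n) {
  delays <- as.integer(delays)
  if (any(delays < 1L)) stop("delays must be >= 1 sample", call. = FALSE)
  if (is.unsorted(delays, strictly = TRUE)) {
    stop("delays must be strictly increasing", call. = FALSE)
  }
  if (any(delays >= n)) {
    stop("delay must be smaller than the series length (", n, ")", call. = FALSE)
  }
  delays
}

# log |V(t + d) - V(t)|, length n - d; -Inf marks |dV| = 0
log_abs_diff <- function(x, d) {
  n <- length(x)
  log(abs(x[(d + 1L):n] - x[1L:(n - d)]))
}

new_kappa_series <- function(values, n_total, delay, delay_ms) {
  structure(
    list(values = values, n_total = n_total, n_valid = length(values),
         delay = delay, delay_ms = delay_ms),
    class = "kappa_series"
  )
}

#' @export
print.kappa_series <- function(x, ...) {
  cat(sprintf("<kappa_series> lag %d samples (%g ms): %d/%d valid timepoints, mean %.4g\n",
              x$delay, if (is.null(x$delay_ms)) NA else x$delay_ms,
              x$n_valid, x$n_total,
              if (x$n_valid) mean(x$values) else NA_real_))
  invisible(x)
}

#' Within-lead information transfer constant series
#'
#' Treats the EEG voltage trace as an information transfer device in which
#' voltage changes scale with the time interval, `|dV| ~ dt^kappa`.  For
#' each timepoint `t` up to `n - delay`,
#' `kappa(t) = log(|V(t + delay) - V(t)|) / log(dt_ms)` where
#' `dt_ms = 1000 * delay / fs` is the lag in milliseconds and `|dV|` is in
#' microvolts.  The ratio of logarithms is base-invariant.  Timepoints with
#' `|dV| = 0` (where the logarithm diverges) are excluded and counted.
#'
#' The lag enters the denominator in milliseconds: with the lag in samples
#' the denominator would vanish at a 1-sample lag, while in ms a 1-sample
#' lag at 250 Hz gives `log(4)`.  A lag of exactly 1 ms is rejected for
#' the same reason.
#'
#' @param signal numeric voltage series in microvolts.
#' @param delay lag in samples (>= 1, < length of `signal`).
#' @param fs sampling rate in Hz.
#' @return A `kappa_series`: per-timepoint values over the valid points,
#'   plus `n_total = n - delay` and `n_valid` bookkeeping.
#' @examples
#' # a ramp with unit step at 250 Hz, lag 2 samples = 8 ms:
#' ks <- kappa_series(seq_len(100), delay = 2, fs = 250)
#' mean_kappa(ks)            # log(2)/log(8)
#' @export
kappa_series <- function(signal, delay, fs) {
  n <- length(signal)
  delay <- check_delays(delay, n)
  stopifnot(length(delay) == 1L, is.numeric(fs), fs > 0)
  dt_ms <- 1000 * delay / fs
  if (abs(dt_ms - 1) < 1e-12) {
    stop("lag of exactly 1 ms makes log(dt) = 0; choose another delay/fs", call. = FALSE)
  }
  la <- log_abs_diff(signal, delay)
  values <- la[is.finite(la)] / log(dt_ms)
  new_kappa_series(values, n_total = n - delay, delay = delay, delay_ms = dt_ms)
}

#' Between-lead information transfer constant ratio series
#'
#' For an ordered pair of leads sharing a lag, the per-timepoint ratio
#' `kappa_itcr(t) = log|dV_source(t)| / log|dV_dest(t)|` measures relative
#' information flow between scalp sites.  The lag cancels out of the value
#' (both within-lead constants share the same `log(dt)` denominator) and
#' only sets the alignment of the differences.  Timepoints are excluded
#' when either lead has `|dV| = 0`, or when `|log|dV_dest|| < eps`
#' (`|dV_dest|` within `eps` of 1 uV makes the denominator vanish).
#'
#' @param source,dest equal-length voltage series in microvolts; `source`
#'   is the numerator lead, `dest` the denominator lead.
#' @param delay lag in samples.
#' @param eps denominator guard on `|log|dV_dest||`.
#' @return A `kappa_series` (the `delay_ms` slot is `NULL`: no time unit
#'   enters the ratio).
#' @examples
#' x <- cumsum(rnorm(500))
#' mean_kappa(kappa_itcr_series(x, x, delay = 3))  # identical leads: 1
#' @export
kappa_itcr_series <- function(source, dest, delay, eps = 1e-8) {
  if (length(source) != length(dest)) {
    stop("source and dest must have the same length", call. = FALSE)
  }
  delay <- check_delays(delay, length(source))
  stopifnot(length(delay) == 1L)
  la1 <- log_abs_diff(source, delay)
  la2 <- log_abs_diff(dest, delay)
  ok <- is.finite(la1) & is.finite(la2) & abs(la2) >= eps
  new_kappa_series(la1[ok] / la2[ok], n_total = length(source) - delay,
                   delay = delay, delay_ms = NULL)
}

#' Segment mean of an information transfer constant series
#'
#' Arithmetic mean over the valid timepoints (the sum divided by
#' `n_valid`, not by the candidate count `n_total`).  With no valid
#' timepoints (e.g. a constant signal) the mean is undefined: `NA` is
#' returned with a warning, never a silent zero.
#'
#' @param series a `kappa_series` from [kappa_series()] or
#'   [kappa_itcr_series()].
#' @return Scalar mean, or `NA_real_` with a warning.
#' @export
mean_kappa <- function(series) {
  stopifnot(inherits(series, "kappa_series"))
  if (series$n_valid == 0L) {
    warning("no valid timepoints: segment mean kappa is undefined (NA)")
    return(NA_real_)
  }
  mean(series$values)
}

#' Information transfer feature table for an epoch
#'
#' Computes the segment-mean within-lead constant for every (lead, lag) on
#' the within grid and the segment-mean between-lead ratio for every
#' ordered lead pair and lag on the between grid.  For `L` leads and `D`
#' lags per grid this yields `L*D` within plus `L*(L-1)*D` between
#' features; 64 leads with 5 lags each give 20,480 features, which is why
#' the study design restricts the modeling stage to the 10-lead subset of
#' [study_leads()] (500 features).
#'
#' Feature names are deterministic: `itm_w_<lead>_<ms>` and
#' `itm_b_<source>_<dest>_<ms>` with the lag rendered in milliseconds.
#' Undefined segment means (no valid timepoints) are emitted as `NA` with
#' a single summarising warning; the modeling stage imputes them from
#' training-set medians.
#'
#' @param epoch an [eeg_record()] (typically from [extract_epoch()]).
#' @param within_delays,between_delays integer sample-lag grids; defaults
#'   [itm_within_grid()] and [itm_between_grid()].
#' @param eps denominator guard passed to the between-lead ratio.
#' @return A tibble with columns `feature`, `kind` ("within"/"between"),
#'   `source`, `dest` (`NA` for within), `delay` (samples), `delay_ms`,
#'   `value`, `n_valid`, `n_total`.
#' @export
itm_features <- function(epoch,
                         within_delays = itm_within_grid(),
                         between_delays = itm_between_grid(),
                         eps = 1e-8) {
  stopifnot(inherits(epoch, "eeg_record"))
  n <- n_timepoints(epoch)
  within_delays <- check_delays(within_delays, n)
  between_delays <- check_delays(between_delays, n)
  labs <- epoch$lead_labels
  L <- length(labs)
  x <- epoch$samples
  fs <- epoch$fs

  rows <- vector("list", length(within_delays) + length(between_delays))
  ri <- 0L
  for (d in within_delays) {
    la <- t(apply(x, 1L, log_abs_diff, d = d))     # L x (n - d)
    if (L == 1L) la <- matrix(la, nrow = 1L)
    dt_ms <- 1000 * d / fs
    if (abs(dt_ms - 1) < 1e-12) stop("within-lead lag of exactly 1 ms not allowed", call. = FALSE)
    fin <- is.finite(la)
    nv <- rowSums(fin)
    sums <- rowSums(ifelse(fin, la, 0))
    val <- ifelse(nv > 0, (sums / nv) / log(dt_ms), NA_real_)
    ri <- ri + 1L
    rows[[ri]] <- tibble::tibble(
      feature = sprintf("itm_w_%s_%g", labs, dt_ms),
      kind = "within", source = labs, dest = NA_character_,
      delay = d, delay_ms = dt_ms,
      value = unname(val), n_valid = unname(as.integer(nv)), n_total = n - d
    )
  }
  for (d in between_delays) {
    la <- t(apply(x, 1L, log_abs_diff, d = d))
    if (L == 1L) la <- matrix(la, nrow = 1L)
    dt_ms <- 1000 * d / fs
    pairs <- expand.grid(dest = seq_len(L), source = seq_len(L))
    pairs <- pairs[pairs$source != pairs$dest, c("source", "dest"), drop = FALSE]
    pairs <- pairs[order(pairs$source, pairs$dest), , drop = FALSE]
    val <- numeric(nrow(pairs)); nv <- integer(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      la1 <- la[pairs$source[i], ]; la2 <- la[pairs$dest[i], ]
      ok <- is.finite(la1) & is.finite(la2) & abs(la2) >= eps
      nv[i] <- sum(ok)
      val[i] <- if (nv[i]) mean(la1[ok] / la2[ok]) else NA_real_
    }
    ri <- ri + 1L
    rows[[ri]] <- tibble::tibble(
      feature = sprintf("itm_b_%s_%s_%g", labs[pairs$source], labs[pairs$dest], dt_ms),
      kind = "between", source = labs[pairs$source], dest = labs[pairs$dest],
      delay = d, delay_ms = dt_ms,
      value = unname(val), n_valid = unname(nv), n_total = n - d
    )
  }
  out <- dplyr::bind_rows(rows)
  n_bad <- sum(is.na(out$value))
  if (n_bad > 0) {
    warning(sprintf("%d ITM feature(s) undefined (no valid timepoints); emitted as NA", n_bad))
  }
  out
}
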