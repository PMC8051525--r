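#' Canonical EEG frequency bands
#'
#' The study band edges: delta 0.1-4, theta 4-7, alpha 8-14, beta 16-31,
#' gamma 32-50 Hz.  Bands are closed intervals and the printed gaps
#' (7-8, 14-16, 31-32 Hz) are deliberately left unassigned.  Note a
#' subtlety for delta on 30 s epochs: Fourier spacing is 1/30 Hz, so the
#' lowest ordinate inside the delta band sits at 2/15 ~ 0.133 Hz.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.1, 4, 8, 16, 32),
    f_hi = c(4, 7, 14, 31, 50)
  )
}

#' Raw periodogram of a voltage series
#'
#' Demeans the signal, optionally applies a split-cosine taper to a
#' fraction of each end ([stats::spec.taper()]), and returns squared FFT
#' ordinates `|X_k|^2 / N` at the positive Fourier frequencies
#' `k * fs / N`, `k = 1 .. floor(N/2)`.  No Welch averaging or smoothing
#' is applied.  The default is untapered; `taper_fraction = 0.1` mimics
#' the classical R periodogram default.
#'
#' @param signal numeric series in microvolts, length >= 8.
#' @param fs sampling rate in Hz.
#' @param taper_fraction proportion of each end tapered, in [0, 0.5).
#' @return A list of class `periodogram` with `freq` (Hz) and `power`
#'   (uV^2) vectors.
#' @examples
#' pg <- periodogram(sin(2 * pi * 10 * (0:7499) / 250), fs = 250)
#' pg$freq[which.max(pg$power)]  # 10 Hz
#' @export
periodogram <- function(signal, fs, taper_fraction = 0) {
  n <- length(signal)
  if (n < 8L) stop("series too short for a periodogram (need >= 8)", call. = FALSE)
  stopifnot(is.numeric(fs), fs > 0, taper_fraction >= 0, taper_fraction < 0.5)
  x <- signal - mean(signal)
  if (taper_fraction > 0) x <- stats::spec.taper(x, p = taper_fraction)
  X <- stats::fft(x)
  k <- seq_len(n %/% 2L)
  structure(
    list(freq = k * fs / n, power = Mod(X[k + 1L])^2 / n, fs = fs, n = n),
    class = "periodogram"
  )
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> %d ordinates, %.4g-%.4g Hz (resolution %.4g Hz)\n",
              length(x$freq), x$freq[1], x$freq[length(x$freq)], x$fs / x$n))
  invisible(x)
}

#' @describeIn periodogram tibble of (freq, power).
#' @param x a `periodogram`.
#' @param ... unused.
#' @export
tidy.periodogram <- function(x, ...) {
  tibble::tibble(freq = x$freq, power = x$power)
}

#' @describeIn periodogram log-power spectrum with the study bands shaded.
#' @param object a `periodogram`.
#' @export
autoplot.periodogram <- function(object, ...) {
  bands <- eeg_bands()
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_rect(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$f_lo, xmax = .data$f_hi,
                                    ymin = 0, ymax = Inf, fill = .data$band),
                       alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_cartesian(xlim = c(0, 60)) +
    ggplot2::labs(x = "frequency (Hz)", y = expression(power~(mu*V^2)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Total spectral power within a band
#'
#' Sum of periodogram ordinates with `f_lo <= f <= f_hi` (closed
#' interval).  A band containing no Fourier frequency returns 0 with a
#' warning.
#'
#' @param pg a [periodogram()].
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Scalar band power in uV^2.
#' @export
band_power <- function(pg, f_lo, f_hi) {
  stopifnot(inherits(pg, "periodogram"))
  if (!(f_lo >= 0 && f_lo < f_hi)) stop("need 0 <= f_lo < f_hi", call. = FALSE)
  if (f_hi > pg$fs / 2 + 1e-9) stop("band exceeds the Nyquist frequency", call. = FALSE)
  inside <- pg$freq >= f_lo & pg$freq <= f_hi
  if (!any(inside)) {
    warning(sprintf("no Fourier frequency inside [%g, %g] Hz; band power 0", f_lo, f_hi))
    return(0)
  }
  sum(pg$power[inside])
}

#' Band-power feature table for an epoch
#'
#' One periodogram per lead, one feature per (lead, band):
#' `ft_<lead>_<band>`.  64 leads x 5 study bands give 320 features; the
#' 10-lead subset gives 50.
#'
#' @param epoch an [eeg_record()].
#' @param bands tibble of band definitions as from [eeg_bands()].
#' @param taper_fraction passed to [periodogram()].
#' @return A tibble with columns `feature`, `lead`, `band`, `value`.
#' @export
ft_features <- function(epoch, bands = eeg_bands(), taper_fraction = 0) {
  stopifnot(inherits(epoch, "eeg_record"))
  stopifnot(all(c("band", "f_lo", "f_hi") %in% names(bands)))
  purrr::map_dfr(epoch$lead_labels, function(lab) {
    pg <- periodogram(epoch$samples[lab, ], fs = epoch$fs,
                      taper_fraction = taper_fraction)
    tibble::tibble(
      feature = sprintf("ft_%s_%s", lab, bands$band),
      lead = lab,
      band = bands$band,
      value = purrr::map2_dbl(bands$f_lo, bands$f_hi, ~ band_power(pg, .x, .y))
    )
  })
}
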