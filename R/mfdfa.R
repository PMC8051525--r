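#' Parameters for multifractal detrended fluctuation analysis
#'
#' Defaults follow the standard published MF-DFA recipe: integer moment
#' orders `q = -5..5` (11 points, always including 0 and 2), 12 log-spaced
#' integer scales between 16 samples and an eighth of the series length
#' (duplicates after rounding are dropped), and linear detrending
#' (`detrend_order = 1`).
#'
#' @param q numeric vector of moment orders; must contain 0 and 2.
#' @param scales ascending integer window sizes in samples, or `NULL` to
#'   build the default grid from the series length at fit time.
#' @param detrend_order polynomial degree removed within each window.
#' @param n_scales,min_scale number of scales and smallest scale for the
#'   default grid.
#' @return A list of class `mfdfa_params`.
#' @export
mfdfa_params <- function(q = -5:5, scales = NULL, detrend_order = 1L,
                         n_scales = 12L, min_scale = 16L) {
  q <- sort(unique(as.numeric(q)))
  if (!any(q == 0) || !any(q == 2)) stop("q grid must contain 0 and 2", call. = FALSE)
  if (length(q) < 3L) stop("q grid needs at least 3 points", call. = FALSE)
  detrend_order <- as.integer(detrend_order)
  if (detrend_order < 0L) stop("detrend_order must be >= 0", call. = FALSE)
  if (!is.null(scales)) {
    scales <- sort(unique(as.integer(scales)))
    if (any(scales < detrend_order + 2L)) {
      stop("every scale must be >= detrend_order + 2", call. = FALSE)
    }
  }
  structure(list(q = q, scales = scales, detrend_order = detrend_order,
                 n_scales = as.integer(n_scales), min_scale = as.integer(min_scale)),
            class = "mfdfa_params")
}

default_scales <- function(n, params) {
  max_scale <- n %/% 8L
  if (max_scale < params$min_scale) {
    stop("series too short for the scale grid (need length >= ",
         8L * params$min_scale, ")", call. = FALSE)
  }
  sort(unique(as.integer(round(exp(seq(log(params$min_scale), log(max_scale),
                                       length.out = params$n_scales))))))
}

#' Profile (cumulative sum) step of MF-DFA
#'
#' `Y(i) = sum_{k <= i} (x_k - mean(x))`.  The final element is zero up to
#' rounding because the deviations telescope.
#'
#' @param signal numeric series, length >= 16.
#' @return Numeric profile of the same length.
#' @export
mfdfa_profile <- function(signal) {
  if (length(signal) < 16L) stop("series too short for MF-DFA (need >= 16)", call. = FALSE)
  cumsum(signal - mean(signal))
}

#' Multifractal fluctuation function at one scale
#'
#' Partitions the profile into `floor(N/s)` non-overlapping windows from
#' each end (so both ends contribute when `N` is not a multiple of `s`),
#' removes a least-squares polynomial of degree `m` in each, and averages
#' the squared residuals into per-window variances `F2`.  The order-`q`
#' fluctuation function is `{mean(F2^(q/2))}^(1/q)` for `q != 0` and the
#' log-average limit `exp(mean(log(F2)) / 2)` at `q = 0`.  Windows with
#' numerically zero residual variance (e.g. an exactly polynomial profile)
#' are floored at a tiny positive constant with a warning so the negative
#' moments stay finite.
#'
#' @param Y profile from [mfdfa_profile()].
#' @param s integer scale (window length), `s >= m + 2`.
#' @param q vector of moment orders.
#' @param m detrending polynomial degree.
#' @param floor_f2 positive floor applied to degenerate window variances.
#' @return Named vector of `F_q(s)`, one per `q`.
#' @export
fluctuation_function <- function(Y, s, q, m = 1L, floor_f2 = 1e-30) {
  s <- as.integer(s); m <- as.integer(m)
  N <- length(Y)
  if (s < m + 2L) stop("scale s must be >= m + 2", call. = FALSE)
  if (s > N) stop("scale exceeds profile length", call. = FALSE)
  Ns <- N %/% s
  idx_fwd <- outer(seq_len(s), (seq_len(Ns) - 1L) * s, `+`)
  idx_bwd <- outer(seq_len(s), N - seq_len(Ns) * s, `+`)
  W <- matrix(Y[cbind(c(idx_fwd, idx_bwd))], nrow = s)   # s x 2Ns
  X <- outer(seq_len(s), 0:m, `^`)
  Q <- qr.Q(qr(X))
  R <- W - Q %*% crossprod(Q, W)
  F2 <- colMeans(R^2)
  if (any(F2 < floor_f2)) {
    warning(sprintf("%d window(s) with ~zero residual variance at scale %d floored",
                    sum(F2 < floor_f2), s))
    F2 <- pmax(F2, floor_f2)
  }
  vapply(q, function(qq) {
    if (qq == 0) exp(mean(log(F2)) / 2) else mean(F2^(qq / 2))^(1 / qq)
  }, numeric(1))
}

#' Multifractal DFA spectrum of a series
#'
#' Runs the full MF-DFA pipeline: profile, window-wise detrended
#' fluctuations over the scale grid, generalized Hurst exponents `h(q)` as
#' least-squares log-log slopes, mass exponents `tau(q) = q h(q) - 1`, and
#' the Legendre transform to the singularity (Hoelder) spectrum via
#' central differences, `alpha = d tau / d q`, `f(alpha) = q alpha - tau`.
#' The central differences drop the two endpoint orders, so `alpha` lives
#' on the interior q grid.
#'
#' The four summary parameters extracted per lead downstream are the mean,
#' minimum and maximum Hoelder exponent and the spectrum width
#' `alpha_max - alpha_min`; a wide spectrum indicates multifractal
#' temporal structure, a narrow one (mono)fractal scaling.
#'
#' @param signal numeric series (voltage trace, cascade measure, ...).
#' @param params an [mfdfa_params()].
#' @return An object of class `mfdfa_spectrum` with elements `q`, `h`,
#'   `tau`, `q_interior`, `alpha`, `f_alpha`, `summary` (named list:
#'   alpha_mean, alpha_min, alpha_max, width), `scales`, `log_fq` (the
#'   `F_q(s)` matrix), `params`.
#' @examples
#' sp <- mfdfa(cumsum(rnorm(4096)))
#' glance(sp)
#' @export
mfdfa <- function(signal, params = mfdfa_params()) {
  stopifnot(inherits(params, "mfdfa_params"))
  Y <- mfdfa_profile(signal)
  N <- length(Y)
  scales <- if (is.null(params$scales)) default_scales(N, params) else params$scales
  if (max(scales) > N %/% 4L) {
    stop("largest scale exceeds a quarter of the series length", call. = FALSE)
  }
  q <- params$q
  Fq <- vapply(scales, function(s) {
    fluctuation_function(Y, s, q, m = params$detrend_order)
  }, numeric(length(q)))                       # |q| x |scales|
  Fq <- matrix(Fq, nrow = length(q), dimnames = list(NULL, NULL))
  ls <- log(scales)
  h <- vapply(seq_along(q), function(i) {
    lf <- log(Fq[i, ])
    if (!all(is.finite(lf))) {
      stop(sprintf("non-finite fluctuation function at q = %g", q[i]), call. = FALSE)
    }
    stats::cov(ls, lf) / stats::var(ls)
  }, numeric(1))
  if (!all(is.finite(h))) {
    stop(sprintf("non-finite h(q) at q = %g", q[which(!is.finite(h))[1]]), call. = FALSE)
  }
  tau <- q * h - 1
  interior <- 2:(length(q) - 1L)
  alpha <- (tau[interior + 1L] - tau[interior - 1L]) / (q[interior + 1L] - q[interior - 1L])
  f_alpha <- q[interior] * alpha - tau[interior]
  structure(
    list(q = q, h = h, tau = tau,
         q_interior = q[interior], alpha = alpha, f_alpha = f_alpha,
         summary = list(alpha_mean = mean(alpha), alpha_min = min(alpha),
                        alpha_max = max(alpha), width = max(alpha) - min(alpha)),
         scales = scales, log_fq = Fq, params = params),
    class = "mfdfa_spectrum"
  )
}

#' @export
print.mfdfa_spectrum <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mfdfa_spectrum> h(2) = %.3f | alpha: mean %.3f, min %.3f, max %.3f, width %.3f\n",
    x$h[x$q == 2], s$alpha_mean, s$alpha_min, s$alpha_max, s$width))
  cat(sprintf("  q in [%g, %g] (%d orders), %d scales in [%d, %d], detrend order %d\n",
              min(x$q), max(x$q), length(x$q), length(x$scales),
              min(x$scales), max(x$scales), x$params$detrend_order))
  invisible(x)
}

#' @describeIn mfdfa one row per interior moment order: q, h, tau, alpha,
#'   f_alpha.
#' @param x an `mfdfa_spectrum`.
#' @param ... unused.
#' @export
tidy.mfdfa_spectrum <- function(x, ...) {
  ix <- match(x$q_interior, x$q)
  tibble::tibble(q = x$q_interior, h = x$h[ix], tau = x$tau[ix],
                 alpha = x$alpha, f_alpha = x$f_alpha)
}

#' @describeIn mfdfa one-row tibble of the four Hoelder summary parameters
#'   plus h(2).
#' @export
glance.mfdfa_spectrum <- function(x, ...) {
  tibble::tibble(h2 = x$h[x$q == 2],
                 alpha_mean = x$summary$alpha_mean,
                 alpha_min = x$summary$alpha_min,
                 alpha_max = x$summary$alpha_max,
                 width = x$summary$width)
}

#' @describeIn mfdfa singularity spectrum `f(alpha)` with an `h(q)` inset
#'   panel.
#' @param object an `mfdfa_spectrum`.
#' @export
autoplot.mfdfa_spectrum <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$alpha, y = .data$f_alpha)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$q)) +
    ggplot2::labs(x = expression(alpha), y = expression(f(alpha)),
                  colour = "q",
                  title = "Singularity spectrum",
                  subtitle = sprintf("width = %.3f, h(2) = %.3f",
                                     object$summary$width, object$h[object$q == 2])) +
    ggplot2::theme_minimal()
}

#' Hoelder summary features for every lead of an epoch
#'
#' Runs [mfdfa()] on each lead and emits the four summary parameters per
#' lead as named features `mfdfa_<lead>_{mean|min|max|width}` — 256
#' features for a 64-lead epoch.  A lead whose spectrum cannot be
#' estimated yields `NA` values with a warning rather than aborting the
#' epoch.
#'
#' @param epoch an [eeg_record()].
#' @param params an [mfdfa_params()].
#' @return A tibble with columns `feature`, `lead`, `param`
#'   (mean/min/max/width), `value`.
#' @export
mfdfa_features <- function(epoch, params = mfdfa_params()) {
  stopifnot(inherits(epoch, "eeg_record"))
  purrr::map_dfr(epoch$lead_labels, function(lab) {
    sm <- tryCatch(mfdfa(epoch$samples[lab, ], params)$summary,
                   error = function(e) {
                     warning("MF-DFA failed on lead ", lab, ": ", conditionMessage(e))
                     list(alpha_mean = NA_real_, alpha_min = NA_real_,
                          alpha_max = NA_real_, width = NA_real_)
                   })
    tibble::tibble(
      feature = sprintf("mfdfa_%s_%s", lab, c("mean", "min", "max", "width")),
      lead = lab,
      param = c("mean", "min", "max", "width"),
      value = c(sm$alpha_mean, sm$alpha_min, sm$alpha_max, sm$width)
    )
  })
}
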