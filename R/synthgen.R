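#' Seeded power-law (1/f^beta) noise
#'
#' Spectral synthesis: Fourier amplitudes proportional to `f^(-beta/2)`
#' with independent random phases, inverted to a real series and
#' standardised to zero mean and unit variance.  `beta = 0` is white
#' noise, `beta = 1` the pink 1/f regime typical of resting EEG,
#' `beta = 2` Brownian-like drift.
#'
#' @param n series length (>= 16).
#' @param beta spectral exponent, in `[-1, 3]`.
#' @param seed integer seed (mandatory; generators are bit-reproducible).
#' @return Numeric series of length `n`.
#' @export
gen_powerlaw_noise <- function(n, beta, seed) {
  if (n < 16L) stop("n must be >= 16", call. = FALSE)
  if (beta < -1 || beta > 3) stop("beta outside [-1, 3]", call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  if (beta == 0) {
    x <- stats::rnorm(n)
  } else {
    nf <- n %/% 2L
    f <- seq_len(nf) / n
    amp <- f^(-beta / 2)
    phase <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    full <- complex(real = numeric(n))
    full[2L:(nf + 1L)] <- spec
    idx <- n - seq_len(nf - if (n %% 2L == 0L) 1L else 0L) + 1L
    full[idx] <- Conj(spec[seq_along(idx)])
    if (n %% 2L == 0L) full[nf + 1L] <- complex(real = amp[nf] * sign(stats::rnorm(1)))
    x <- Re(stats::fft(full, inverse = TRUE))
  }
  as.numeric(scale(x))
}

#' Seeded fractional Gaussian noise
#'
#' Circulant-embedding (Davies-Harte) synthesis of fGn with Hurst
#' exponent `H`: the target autocovariance
#' `g(k) = (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)) / 2` is embedded in a
#' circulant matrix whose eigenvalues (obtained by FFT) drive an exact
#' Gaussian sample.  `H = 0.5` reduces to white noise; the series is a
#' monofractal reference for the multifractal estimators.
#'
#' @param n series length.
#' @param hurst Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return Numeric series with `method` attribute `"circulant-embedding"`;
#'   unit-variance by construction (`g(0) = 1`).
#' @export
gen_fgn <- function(n, hurst, seed) {
  if (hurst <= 0 || hurst >= 1) stop("hurst must be in (0, 1)", call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  if (abs(hurst - 0.5) < 1e-12) {
    out <- stats::rnorm(n)
  } else {
    M <- 2^ceiling(log2(n))
    k <- 0:M
    g <- (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) + abs(k - 1)^(2 * hurst)) / 2
    circ <- c(g, g[M:2])                          # length 2M
    lambda <- Re(stats::fft(circ))
    lambda[lambda < 0] <- 0                       # clip rounding negatives
    m2 <- 2L * M
    z <- complex(real = stats::rnorm(m2), imaginary = stats::rnorm(m2))
    out <- Re(stats::fft(sqrt(lambda) * z))[seq_len(n)] / sqrt(m2)
  }
  attr(out, "method") <- "circulant-embedding"
  attr(out, "hurst") <- hurst
  out
}

#' Binomial multiplicative cascade
#'
#' A dyadic multiplicative measure: starting from unit mass, each cell is
#' repeatedly split in two with weights `p` and `1 - p` assigned in
#' random order, for `levels` generations.  The resulting series of
#' `2^levels` cell masses is the standard closed-form multifractal
#' oracle: its generalized Hurst exponent is
#' `h(q) = 1/q - ln(p^q + (1-p)^q) / (q ln 2)` and its singularity
#' spectrum has theoretical width `log2(p / (1 - p))`.
#'
#' @param levels number of dyadic generations (>= 10).
#' @param p heavy weight, `0.5 < p < 1` (`p = 0.5` degenerates to a
#'   uniform, monofractal measure and is warned about).
#' @param seed integer seed.
#' @return Measure series of length `2^levels` summing to 1, with
#'   attributes `h_theory` (function of q), `width_theory`, `p`.
#' @export
gen_binomial_cascade <- function(levels, p, seed) {
  if (levels < 10L) stop("levels must be >= 10", call. = FALSE)
  if (p <= 0.5 || p >= 1) {
    if (abs(p - 0.5) < 1e-12) warning("p = 0.5 gives a degenerate (monofractal) cascade")
    else stop("p must be in (0.5, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  x <- 1
  for (l in seq_len(levels)) {
    flip <- stats::runif(length(x)) < 0.5
    w1 <- ifelse(flip, p, 1 - p)
    x <- as.vector(rbind(x * w1, x * (1 - w1)))
  }
  attr(x, "h_theory") <- function(q) cascade_h_theory(q, p)
  attr(x, "width_theory") <- log2(p / (1 - p))
  attr(x, "p") <- p
  x
}

#' @rdname gen_binomial_cascade
#' @param q moment order(s), nonzero.
#' @return `cascade_h_theory()`: theoretical `h(q)` of the binomial
#'   measure.
#' @export
cascade_h_theory <- function(q, p) {
  stopifnot(all(q != 0))
  1 / q - log(p^q + (1 - p)^q) / (q * log(2))
}

#' Specification of a synthetic cohort
#'
#' The generator emulates the study's data shape: by default 12 subjects,
#' 64 leads at 250 Hz for 300 s of 1/f background with band-limited
#' oscillations.  Subject-level latent amplitudes persist across the
#' whole recording, so the two-epoch train/test design carries signal;
#' scores are a linear function of the declared driver latents plus
#' Gaussian noise.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_leads,fs,duration recording geometry (leads, Hz, seconds).
#' @param noise_beta spectral exponent of the background noise.
#' @param background_sd background amplitude in uV.
#' @param osc_amp baseline oscillation amplitude in uV applied to every
#'   (lead, band).
#' @param coupling optional tibble `(source, dest, gain, lag, noise_sd)`
#'   of lead labels: each dest lead is rebuilt as
#'   `gain * lag(source) + noise`.  A zero-lag cycle is rejected.
#' @param drivers tibble `(subscore, lead, band, effect)`: each row makes
#'   the named subscore depend on that lead's band-limited amplitude with
#'   the given effect size (score units per unit latent).
#' @param score_noise_sd additive Gaussian noise on every subscore.
#' @param seed integer seed (mandatory).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12L, n_leads = 64L, fs = 250,
                        duration = 300, noise_beta = 1,
                        background_sd = 10, osc_amp = 2,
                        coupling = NULL, drivers = NULL,
                        score_noise_sd = 0.25, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_subjects >= 3L, n_leads >= 1L, fs > 0, duration * fs >= 32)
  if (!is.null(coupling)) {
    stopifnot(all(c("source", "dest", "gain", "lag") %in% names(coupling)))
    if (!"noise_sd" %in% names(coupling)) coupling$noise_sd <- 0
    if (any(coupling$lag >= duration * fs)) stop("coupling lag exceeds recording", call. = FALSE)
    check_zero_lag_cycles(coupling)
  }
  if (!is.null(drivers)) {
    stopifnot(all(c("subscore", "lead", "band", "effect") %in% names(drivers)))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_leads = as.integer(n_leads),
         fs = fs, duration = duration, noise_beta = noise_beta,
         background_sd = background_sd, osc_amp = osc_amp,
         coupling = coupling, drivers = drivers,
         score_noise_sd = score_noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

check_zero_lag_cycles <- function(coupling) {
  zl <- coupling[coupling$lag == 0, , drop = FALSE]
  if (!nrow(zl)) return(invisible(TRUE))
  # DFS for a cycle restricted to zero-lag edges
  adj <- split(as.character(zl$dest), as.character(zl$source))
  state <- new.env()
  visit <- function(v) {
    s <- get0(v, envir = state, ifnotfound = 0L)
    if (s == 1L) stop("coupling graph has a zero-lag cycle", call. = FALSE)
    if (s == 2L) return(invisible())
    assign(v, 1L, envir = state)
    for (w in adj[[v]] %||% character(0)) visit(w)
    assign(v, 2L, envir = state)
  }
  for (v in names(adj)) visit(v)
  invisible(TRUE)
}

band_centre <- function(band) {
  b <- eeg_bands()
  i <- match(band, b$band)
  if (anyNA(i)) stop("unknown band: ", paste(band[is.na(i)], collapse = ", "), call. = FALSE)
  (b$f_lo[i] + b$f_hi[i]) / 2
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per subject, each lead is `background_sd` x power-law noise plus a
#' sinusoid at each band centre.  For (lead, band) pairs named in the
#' driver table, the subject's oscillation amplitude is
#' `osc_amp * (0.2 + 2.8 * u)` with a persistent latent `u ~ U(0, 1)`;
#' all other pairs use the constant baseline `osc_amp`.  Coupled leads
#' are rebuilt as `gain * lag(source) + noise`.  Subscores named in the
#' driver table equal `effect * u + N(0, score_noise_sd)`; the rest are
#' pure noise.  Everything is reproducible from `spec$seed` and all
#' latent ground truth is returned.
#'
#' @param spec a [cohort_spec()].
#' @return A list: `records` (named list of [eeg_record()]s), `scores`
#'   (tibble), `truth` (list with `latents` tibble, `drivers`,
#'   `coupling`, `spec`).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  labs <- as.character(seq_len(spec$n_leads))
  tvec <- (seq_len(n) - 1) / spec$fs
  bands <- eeg_bands()$band
  subj_ids <- sprintf("S%02d", seq_len(spec$n_subjects))

  driven <- if (is.null(spec$drivers)) {
    tibble::tibble(lead = character(0), band = character(0))
  } else unique(spec$drivers[c("lead", "band")])

  latents <- list()
  records <- list()
  scores_rows <- list()
  for (si in seq_along(subj_ids)) {
    id <- subj_ids[si]
    u <- stats::runif(nrow(driven))
    if (nrow(driven)) {
      latents[[id]] <- tibble::tibble(subject_id = id, lead = driven$lead,
                                      band = driven$band, u = u)
    }
    x <- matrix(0, nrow = spec$n_leads, ncol = n, dimnames = list(labs, NULL))
    for (li in seq_len(spec$n_leads)) {
      bg <- gen_powerlaw_noise(n, spec$noise_beta,
                               seed = spec$seed + 7919L * si + 104729L * li)
      sig <- spec$background_sd * bg
      for (b in bands) {
        di <- which(driven$lead == labs[li] & driven$band == b)
        amp <- if (length(di)) spec$osc_amp * (0.2 + 2.8 * u[di[1]]) else spec$osc_amp
        sig <- sig + amp * sin(2 * pi * band_centre(b) * tvec + stats::runif(1, 0, 2 * pi))
      }
      x[li, ] <- sig
    }
    if (!is.null(spec$coupling)) {
      cp <- spec$coupling
      for (ci in seq_len(nrow(cp))) {
        src <- x[as.character(cp$source[ci]), ]
        lag <- cp$lag[ci]
        shifted <- if (lag > 0) c(src[(n - lag + 1):n], src[1:(n - lag)]) else src
        noise <- if (cp$noise_sd[ci] > 0) {
          cp$noise_sd[ci] * gen_powerlaw_noise(n, spec$noise_beta,
                                               seed = spec$seed + 15485863L * si + ci)
        } else 0
        x[as.character(cp$dest[ci]), ] <- cp$gain[ci] * shifted + noise
      }
    }
    records[[id]] <- eeg_record(x, fs = spec$fs, lead_labels = labs, subject_id = id)

    sc <- stats::setNames(stats::rnorm(length(subscore_names()), 0, 1), subscore_names())
    if (!is.null(spec$drivers)) {
      for (di in seq_len(nrow(spec$drivers))) {
        row <- spec$drivers[di, ]
        ui <- which(driven$lead == row$lead & driven$band == row$band)
        sc[row$subscore] <- row$effect * u[ui] +
          stats::rnorm(1, 0, spec$score_noise_sd)
      }
    }
    scores_rows[[id]] <- tibble::as_tibble(c(list(subject_id = id), as.list(sc)))
  }
  list(
    records = records,
    scores = dplyr::bind_rows(scores_rows),
    truth = list(latents = dplyr::bind_rows(latents),
                 drivers = spec$drivers, coupling = spec$coupling, spec = spec)
  )
}
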