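#' Multichannel EEG recording
#'
#' `eeg_record()` bundles a leads-by-timepoints voltage matrix with its
#' sampling rate and lead labels.  All voltages are microvolts (uV)
#' throughout the package: the within-lead information transfer constant
#' depends on the absolute size of |dV|, so a single fixed unit is required
#' for reproducibility, and the file readers convert on ingestion.
#'
#' @param samples numeric matrix, one row per lead, one column per
#'   timepoint, in uV.  A plain vector is treated as a single lead.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_labels character vector of unique lead identifiers, one per
#'   row.  Defaults to `"1" .. "L"`.
#' @param subject_id opaque subject identifier string.
#'
#' @return An object of class `eeg_record`.
#' @examples
#' rec <- eeg_record(matrix(rnorm(500), nrow = 2), fs = 250)
#' rec
#' eeg_duration(rec)
#' @export
eeg_record <- function(samples, fs, lead_labels = NULL, subject_id = NA_character_) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (leads x timepoints)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (ncol(samples) < 2L) {
    stop("each lead needs at least 2 timepoints", call. = FALSE)
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("`samples` contains non-finite values", call. = FALSE)
  }
  if (is.null(lead_labels)) {
    lead_labels <- as.character(seq_len(nrow(samples)))
  }
  lead_labels <- as.character(lead_labels)
  if (length(lead_labels) != nrow(samples)) {
    stop("`lead_labels` must have one entry per lead", call. = FALSE)
  }
  if (anyDuplicated(lead_labels)) {
    stop("`lead_labels` must be unique", call. = FALSE)
  }
  dimnames(samples) <- list(lead_labels, NULL)
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      lead_labels = lead_labels,
      subject_id = as.character(subject_id)
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d leads x %d samples @ %g Hz (%.6g s)%s\n",
    n_leads(x), n_timepoints(x), x$fs, eeg_duration(x),
    if (!is.na(x$subject_id)) paste0(" subject ", x$subject_id) else ""
  ))
  win <- attr(x, "epoch_window")
  if (!is.null(win)) {
    cat(sprintf("  epoch window: [%g, %g) s of parent recording\n", win[1], win[2]))
  }
  cat("  leads: ", paste(utils::head(x$lead_labels, 12), collapse = ", "),
      if (n_leads(x) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname eeg_record
#' @param x,record an `eeg_record`.
#' @export
eeg_duration <- function(record) n_timepoints(record) / record$fs

#' @rdname eeg_record
#' @export
n_leads <- function(record) nrow(record$samples)

#' @rdname eeg_record
#' @export
n_timepoints <- function(record) ncol(record$samples)

#' @describeIn eeg_record long tibble (time_s, lead, uV), convenient for ggplot2.
#' @param ... unused.
#' @export
as_tibble.eeg_record <- function(x, ...) {
  tibble::tibble(
    time_s = rep((seq_len(n_timepoints(x)) - 1) / x$fs, each = n_leads(x)),
    lead = rep(x$lead_labels, times = n_timepoints(x)),
    uV = as.vector(x$samples)
  )
}

#' Extract a time epoch from a recording
#'
#' Windows are half-open `[start_s, end_s)` with 0-based time, so a 30 s
#' window at 250 Hz is exactly 7500 samples.  The study design uses two
#' such epochs per recording, `[90, 120)` s for training and `[210, 240)` s
#' for out-of-sample testing; [study_windows()] returns both.
#'
#' @param record an [eeg_record()].
#' @param start_s,end_s window bounds in seconds from recording onset,
#'   `0 <= start_s < end_s <= duration`.
#' @return An `eeg_record` restricted to the window, carrying an
#'   `epoch_window` attribute.
#' @examples
#' rec <- eeg_record(matrix(rnorm(2 * 250 * 60), nrow = 2), fs = 250)
#' ep <- extract_epoch(rec, 10, 40)
#' n_timepoints(ep)  # 7500
#' @export
extract_epoch <- function(record, start_s, end_s) {
  stopifnot(inherits(record, "eeg_record"))
  if (!is.numeric(start_s) || !is.numeric(end_s) || start_s < 0 || start_s >= end_s) {
    stop("need 0 <= start_s < end_s", call. = FALSE)
  }
  dur <- eeg_duration(record)
  if (end_s > dur + 1e-9) {
    stop(sprintf("window [%g, %g) exceeds recording duration %g s",
                 start_s, end_s, dur), call. = FALSE)
  }
  i0 <- round(start_s * record$fs)       # 0-based first sample, included
  i1 <- round(end_s * record$fs)         # 0-based first sample excluded
  out <- eeg_record(
    record$samples[, (i0 + 1):i1, drop = FALSE],
    fs = record$fs,
    lead_labels = record$lead_labels,
    subject_id = record$subject_id
  )
  attr(out, "epoch_window") <- c(start_s, end_s)
  out
}

#' @rdname extract_epoch
#' @return `study_windows()`: a named list of the two default 30 s windows.
#' @export
study_windows <- function() {
  list(train = c(90, 120), test = c(210, 240))
}

#' Restrict a recording to a subset of leads
#'
#' Returns the record restricted to `labels`, in the requested order.
#' [study_leads()] returns the default 10-lead scalp-covering subset used
#' for the information-transfer analysis (right frontal 3/56, left frontal
#' 9/19, anterior/posterior midline 6/36, right parietal 40/46, left
#' parietal 26/31).
#'
#' @inheritParams extract_epoch
#' @param labels character vector of lead labels to keep, all present in
#'   the record.
#' @export
select_leads <- function(record, labels) {
  stopifnot(inherits(record, "eeg_record"))
  labels <- as.character(labels)
  missing <- setdiff(labels, record$lead_labels)
  if (length(missing)) {
    stop("unknown lead label(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- eeg_record(
    record$samples[labels, , drop = FALSE],
    fs = record$fs,
    lead_labels = labels,
    subject_id = record$subject_id
  )
  attr(out, "epoch_window") <- attr(record, "epoch_window")
  out
}

#' @rdname select_leads
#' @export
study_leads <- function() {
  c("3", "56", "9", "19", "6", "36", "40", "46", "26", "31")
}
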