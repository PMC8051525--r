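#' Read a delimited numeric matrix as an EEG recording
#'
#' Expects one row per timepoint and one column per lead, with an optional
#' header row of lead labels.  The delimiter (comma, tab or whitespace) is
#' inferred from the first line.  Values are taken to be microvolts.
#'
#' @param path path to a delimited text file.
#' @param fs sampling rate in Hz.
#' @param labels optional lead labels; overrides any header.
#' @param subject_id optional subject identifier.
#' @return An [eeg_record()].
#' @export
read_matrix <- function(path, fs, labels = NULL, subject_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  nf <- utils::count.fields(path, sep = sep)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) != 1L) {
    stop("ragged rows: field counts ", paste(unique(nf), collapse = "/"), call. = FALSE)
  }
  first_fields <- scan(text = first, what = character(), sep = if (sep == "") "" else sep,
                       quiet = TRUE, strip.white = TRUE)
  has_header <- anyNA(suppressWarnings(as.numeric(first_fields)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          colClasses = "numeric", check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric cells in ", path, call. = FALSE)
  if (is.null(labels)) {
    labels <- if (has_header) colnames(df) else as.character(seq_len(ncol(m)))
  }
  eeg_record(t(m), fs = fs, lead_labels = labels, subject_id = subject_id)
}

#' @rdname read_matrix
#' @param record an [eeg_record()] to write (CSV, header row of lead labels,
#'   one row per timepoint).
#' @export
write_matrix <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  m <- t(record$samples)
  colnames(m) <- record$lead_labels
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

# ---- EDF (European Data Format) ------------------------------------------
# Minimal continuous-EDF subset: fixed 256-byte main header, 256 bytes per
# signal header, data records of 16-bit little-endian integers with linear
# digital -> physical scaling.  Annotation channels are dropped on read.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_unit_to_uV <- function(dim) {
  dim <- trimws(dim)
  switch(tolower(dim), "uv" = 1, "\u00b5v" = 1, "mv" = 1e3, "v" = 1e6, 1)
}

#' Read a European Data Format (EDF) file
#'
#' Reads a continuous EDF recording into an [eeg_record()], converting the
#' stored physical unit (uV, mV or V) to microvolts.  All data signals must
#' share a single sampling rate; annotation channels are ignored.
#'
#' @param path path to an EDF file.
#' @param subject_id optional subject identifier; defaults to the header's
#'   local patient identification field.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  if (nchar(hdr) < 256L) stop("not an EDF file (truncated header): ", path, call. = FALSE)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  patient <- field(hdr, 9, 80)
  n_rec <- as.integer(field(hdr, 237, 8))
  rec_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 1L) stop("EDF file has zero signals: ", path, call. = FALSE)
  if (is.na(n_rec) || n_rec < 1L || is.na(rec_dur) || rec_dur <= 0) {
    stop("unreadable EDF header (records/duration): ", path, call. = FALSE)
  }
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  # per-signal fields are stored blockwise: ns labels, ns transducers, ...
  off <- 1L
  take <- function(len) {
    out <- vapply(seq_len(ns) - 1L, function(i) {
      trimws(substr(sig_hdr, off + i * len, off + i * len + len - 1L))
    }, character(1))
    off <<- off + ns * len
    out
  }
  labels <- take(16L); take(80L)                 # transducer, unused
  phys_dim <- take(8L)
  phys_min <- as.numeric(take(8L)); phys_max <- as.numeric(take(8L))
  dig_min <- as.numeric(take(8L)); dig_max <- as.numeric(take(8L))
  take(80L)                                      # prefiltering, unused
  spr <- as.integer(take(8L))                    # samples per data record
  keep <- !grepl("^EDF Annotations", labels)
  if (!any(keep)) stop("EDF file has zero data signals: ", path, call. = FALSE)
  if (length(unique(spr[keep])) != 1L || length(unique(rec_dur)) != 1L) {
    stop("mixed sampling rates across EDF signals", call. = FALSE)
  }
  fs <- spr[keep][1] / rec_dur
  raw_n <- sum(spr) * n_rec
  dat <- readBin(con, "integer", n = raw_n, size = 2L, endian = "little", signed = TRUE)
  if (length(dat) < raw_n) stop("EDF data section truncated: ", path, call. = FALSE)
  out <- matrix(0, nrow = sum(keep), ncol = spr[keep][1] * n_rec)
  starts <- cumsum(c(0L, spr))[seq_len(ns)]
  rec_len <- sum(spr)
  ki <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    ki <- ki + 1L
    idx <- as.vector(outer(seq_len(spr[s]), (seq_len(n_rec) - 1L) * rec_len, `+`) + starts[s])
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    out[ki, ] <- ((dat[idx] - dig_min[s]) * gain + phys_min[s]) * edf_unit_to_uV(phys_dim[s])
  }
  eeg_record(out, fs = fs, lead_labels = labels[keep],
             subject_id = if (is.null(subject_id)) {
               if (nzchar(patient)) patient else NA_character_
             } else subject_id)
}

#' @rdname read_edf
#' @param record an [eeg_record()] to serialise.  Record duration is fixed
#'   at 1 s, so `fs` must be a whole number and any trailing partial second
#'   is dropped with a warning.  Samples are quantised to 16-bit integers
#'   over each lead's physical range.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  n <- n_timepoints(record)
  n_rec <- n %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)", call. = FALSE)
  if (n_rec * fs < n) {
    warning(sprintf("dropping %d trailing samples (partial final 1 s record)",
                    n - n_rec * fs))
  }
  x <- record$samples[, seq_len(n_rec * fs), drop = FALSE]
  L <- nrow(x)
  phys_min <- apply(x, 1, min); phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1; phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  subj <- if (is.na(record$subject_id)) "X" else record$subject_id
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(subj, 80), edf_pad("itmeeg export", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + L), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(L, 4)
  )
  writeChar(hdr, con, eos = NULL)
  num8 <- function(v) vapply(v, function(z) edf_pad(formatC(z, format = "g", digits = 7), 8),
                             character(1))
  writeChar(paste0(
    paste(edf_pad(record$lead_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), L), collapse = ""),
    paste(rep(edf_pad("uV", 8), L), collapse = ""),
    paste(num8(phys_min), collapse = ""),
    paste(num8(phys_max), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), L), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), L), collapse = ""),
    paste(rep(edf_pad("", 80), L), collapse = ""),
    paste(rep(edf_pad(fs, 8), L), collapse = ""),
    paste(rep(edf_pad("", 32), L), collapse = "")
  ), con, eos = NULL)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(L)) {
      dig <- round((x[s, cols] - phys_min[s]) * gain[s] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a cognitive score table
#'
#' One row per subject: a `subject_id` column plus one numeric column per
#' subscore.  The package's study set of subscores is the D-KEFS Tower
#' test battery: ACH (total achievement), FMT (mean first move time), MAR
#' (move accuracy ratio), RVPI (rule violations per item), TPM (time per
#' move) and TRV (total rule violations).
#'
#' @param path CSV file path.
#' @param subscores declared set of admissible subscore names; columns
#'   outside `subject_id` must be drawn from it.
#' @return A tibble, one row per subject.
#' @export
read_scores <- function(path, subscores = subscore_names()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("score table needs a subject_id column", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in score table", call. = FALSE)
  bad <- setdiff(setdiff(names(df), "subject_id"), subscores)
  if (length(bad)) {
    stop("unknown subscore column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_scores
#' @export
subscore_names <- function() c("ACH", "FMT", "MAR", "RVPI", "TPM", "TRV")
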