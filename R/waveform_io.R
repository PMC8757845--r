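#' @useDynLib pvascore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

CHANNEL_NAMES <- c("pressure", "flow", "belt_thorax", "belt_abdomen")

# Zero-phase filtering with odd-reflection padding at both ends, so edge
# transients of the forward-backward pass stay outside the signal.
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  np <- min(n - 1L, as.integer(pad))
  if (np < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  as.numeric(y[(np + 1):(np + n)])
}

#' Multichannel respiratory recording
#'
#' Container for uniformly sampled airway-pressure, flow and (optional)
#' respiratory-belt waveforms. Pressure is in cmH2O, flow in L/min; belt
#' channels are in arbitrary units. All channels share one sampling rate and
#' one length.
#'
#' @param channels Named list of equal-length numeric vectors. Must contain
#'   at least \code{pressure} and \code{flow}; \code{belt_thorax} and
#'   \code{belt_abdomen} are optional.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param units Named character vector of units per channel. Defaults to
#'   cmH2O for pressure, L/min for flow, "a.u." for belts.
#' @param start_time Time of the first sample in seconds (default 0). Sample
#'   \code{i} (0-based) covers the half-open interval
#'   \code{[start_time + i/rate, start_time + (i+1)/rate)}.
#' @return An object of class \code{waveform_recording}.
#' @export
waveform_recording <- function(channels, sampling_rate, units = NULL,
                               start_time = 0) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a named list of numeric vectors")
  bad <- setdiff(names(channels), CHANNEL_NAMES)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (!all(c("pressure", "flow") %in% names(channels)))
    stop("format error: recording must contain 'pressure' and 'flow' channels")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("format error: all channels must have equal length")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("format error: sampling rate must be a single positive number")
  default_units <- c(pressure = "cmH2O", flow = "L/min",
                     belt_thorax = "a.u.", belt_abdomen = "a.u.")
  u <- default_units[names(channels)]
  if (!is.null(units)) u[names(units)] <- units
  structure(list(channels = lapply(channels, as.numeric),
                 sampling_rate = as.numeric(sampling_rate),
                 units = u, start_time = as.numeric(start_time)),
            class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("<waveform_recording> %d channel(s), %.6g Hz, %.6g s\n",
              length(x$channels), x$sampling_rate, rec_duration(x)))
  for (nm in names(x$channels))
    cat(sprintf("  %-13s %8d samples  [%s]\n", nm, length(x$channels[[nm]]),
                x$units[[nm]]))
  invisible(x)
}

#' Number of samples per channel
#' @param rec A \code{waveform_recording}.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

#' Recording duration in seconds
#' @param rec A \code{waveform_recording}.
#' @return Duration (n samples / rate).
#' @export
rec_duration <- function(rec) n_samples(rec) / rec$sampling_rate

#' Sample times of a recording
#' @param rec A \code{waveform_recording}.
#' @return Numeric vector of times (s) of each sample.
#' @export
rec_times <- function(rec)
  rec$start_time + (seq_len(n_samples(rec)) - 1) / rec$sampling_rate

#' Ventilator settings
#'
#' The three settings the scorer uses: expiratory positive airway pressure
#' (EPAP), inspiratory positive airway pressure (IPAP), both in cmH2O, and
#' the backup frequency \code{f_bck} in cycles/min (the minimum machine-cycle
#' rate: if no effort triggers the ventilator within 60/f_bck seconds of the
#' previous cycle onset, a backup cycle is delivered).
#'
#' @param epap EPAP in cmH2O (>= 0).
#' @param ipap IPAP in cmH2O (> epap).
#' @param f_bck Backup frequency in cycles/min (> 0).
#' @return An object of class \code{ventilator_settings}.
#' @export
ventilator_settings <- function(epap, ipap, f_bck) {
  if (!is.finite(epap) || epap < 0) stop("epap must be >= 0")
  if (!is.finite(ipap) || ipap <= epap) stop("ipap must exceed epap")
  if (!is.finite(f_bck) || f_bck <= 0) stop("f_bck must be > 0")
  structure(list(epap = epap, ipap = ipap, f_bck = f_bck),
            class = "ventilator_settings")
}

#' Read a waveform recording from delimited text
#'
#' The file dialect is one comment line \code{# rate_hz=<r>}, an optional
#' \code{# units=<u1>,<u2>,...} line, a column-name line, then tab- or
#' comma-delimited numeric rows. Column names must be drawn from
#' \code{pressure}, \code{flow}, \code{belt_thorax}, \code{belt_abdomen}
#' (an optional \code{time} column is checked for uniformity and dropped).
#' Flow given in L/s is converted to the canonical internal unit L/min.
#'
#' @param path Path to the text file.
#' @return A \code{waveform_recording}.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  lines <- readLines(path, n = 4L)
  if (!length(lines)) stop("format error: empty file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("rate_hz=[0-9.eE+-]+", hdr))
  m <- m[lengths(regmatches(hdr, gregexpr("rate_hz=", hdr))) > 0]
  if (!length(m)) stop("format error: missing '# rate_hz=' header line")
  rate <- as.numeric(sub("rate_hz=", "", m[[1]]))
  if (!is.finite(rate) || rate <= 0)
    stop("format error: sampling rate must be a single positive number")
  units <- NULL
  mu <- grep("units=", hdr, value = TRUE)
  if (length(mu))
    units <- strsplit(sub(".*units=", "", mu[[1]]), ",")[[1]]
  first_data <- lines[!grepl("^#", lines)][1]
  sep <- if (grepl("\t", first_data)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE)
  if (!is.null(units)) {
    if (length(units) != ncol(df))
      stop("format error: units header does not match column count")
    names(units) <- names(df)
  }
  if ("time" %in% names(df)) {
    tt <- df$time
    if (nrow(df) > 2 && max(abs(diff(diff(tt)))) > 1e-6)
      stop("format error: non-uniform time column")
    df$time <- NULL
    if (!is.null(units)) units <- units[names(units) != "time"]
  }
  channels <- as.list(df)
  if ("flow" %in% names(channels) && !is.null(units) &&
      grepl("^l/s$|^L/s$", units[["flow"]])) {
    channels$flow <- channels$flow * 60
    units[["flow"]] <- "L/min"
  }
  waveform_recording(channels, rate, units = units)
}

#' Write a waveform recording to delimited text
#'
#' Emits the dialect read by [read_recording()]: a \code{# rate_hz=} line, a
#' \code{# units=} line, tab-separated column names and data rows.
#'
#' @param rec A \code{waveform_recording}.
#' @param path Output path.
#' @param digits Significant digits for the values (default 7).
#' @return Invisibly, \code{path}.
#' @export
write_recording <- function(rec, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", rec$sampling_rate), con)
  writeLines(paste0("# units=", paste(rec$units[names(rec$channels)],
                                      collapse = ",")), con)
  df <- as.data.frame(lapply(rec$channels, signif, digits = digits))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Metadata of a recording as JSON
#'
#' @param rec A \code{waveform_recording}.
#' @param path Optional path; if given the JSON is written there.
#' @return JSON string (invisibly if written to file).
#' @export
recording_metadata_json <- function(rec, path = NULL) {
  meta <- list(channels = names(rec$channels),
               units = as.list(rec$units[names(rec$channels)]),
               sampling_rate = rec$sampling_rate,
               start_time = rec$start_time,
               n_samples = n_samples(rec),
               duration = rec_duration(rec))
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# Band-limited resampling of one channel: zero-phase Butterworth
# anti-aliasing below the target Nyquist when decimating, then spline
# interpolation onto the new grid.
resample_channel <- function(x, f_in, f_out) {
  n_out <- round(length(x) * f_out / f_in)
  if (f_out < f_in) {
    wc <- 0.9 * (f_out / 2) / (f_in / 2)   # normalized cutoff, margin below Nyquist
    bf <- signal::butter(6, wc, type = "low")
    mu <- mean(x)
    x <- mu + filtfilt_padded(bf, x - mu, round(4 * f_in / f_out) * 8)
  }
  t_in <- (seq_along(x) - 1) / f_in
  t_out <- (seq_len(n_out) - 1) / f_out
  stats::spline(t_in, x, xout = t_out, method = "natural")$y
}

#' Resample a recording to a new rate
#'
#' Band-limited resampling of every channel: when decimating, channels are
#' first low-pass filtered (zero-phase Butterworth with cutoff just below the
#' target Nyquist frequency) and then interpolated onto the target grid, so
#' content below \code{f_target/2} is preserved and higher frequencies do not
#' alias. Duration is preserved within one output sample period. Resampling
#' at the native rate is the exact identity.
#'
#' @param rec A \code{waveform_recording}.
#' @param f_target Target rate in Hz (> 0).
#' @return A \code{waveform_recording} at \code{f_target} Hz.
#' @export
resample_recording <- function(rec, f_target) {
  if (!is.numeric(f_target) || length(f_target) != 1L ||
      !is.finite(f_target) || f_target <= 0)
    stop("f_target must be a single positive number")
  if (f_target == rec$sampling_rate) return(rec)
  channels <- lapply(rec$channels, resample_channel,
                     f_in = rec$sampling_rate, f_out = f_target)
  waveform_recording(channels, f_target, units = rec$units,
                     start_time = rec$start_time)
}

#' Remove long-term drift from a belt signal
#'
#' Zero-phase high-pass filter (2nd-order Butterworth, applied forwards and
#' backwards) that removes baseline drift below \code{cutoff} while leaving
#' the breathing band (0.1-1 Hz) essentially untouched. Belt channels are
#' advisory (a visual aid for reviewers); the automatic classifier never uses
#' them.
#'
#' @param x Numeric signal.
#' @param rate Sampling rate in Hz.
#' @param cutoff High-pass cutoff in Hz (default 0.05, well below breathing
#'   frequencies).
#' @return Filtered signal, approximately zero-mean.
#' @export
detrend_belt <- function(x, rate, cutoff = 0.05) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be > 0")
  # remove the best-fit line first: the high-pass then only has to act on
  # the residual, which keeps filter edge transients negligible
  tt <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, tt), x)
  r <- unname(fit$residuals)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "high")
  filtfilt_padded(bf, r, round(2 * rate / cutoff))
}
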