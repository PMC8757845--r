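LABELS <- c("N", "Bck", "DT", "AT", "IE", "X")

#' Scored recording
#'
#' An ordered sequence of counted units, each labelled N (normal), Bck
#' (backup), DT (double-trigger pair, counted once), AT (auto-trigger), IE
#' (ineffective effort) or X (discarded), together with the derived counts
#' and the asynchrony index.
#'
#' @param units Data frame with columns \code{onset}, \code{end},
#'   \code{label}.
#' @param duration Recording duration (s).
#' @param f_breath Breathing frequency (breaths/min) or NA.
#' @param warnings Character vector of scoring warnings.
#' @return An object of class \code{scored_recording} with elements
#'   \code{units}, \code{counts} (named: N_tot, N_N, N_Bck, N_DT, N_AT,
#'   N_IE, N_X), \code{ai} (percent, full precision; NA when N_tot = 0),
#'   \code{f_breath}, \code{duration}, \code{warnings}.
#' @export
scored_recording <- function(units, duration, f_breath = NA_real_,
                             warnings = character()) {
  stopifnot(all(c("onset", "end", "label") %in% names(units)))
  if (!all(units$label %in% LABELS))
    stop("labels must be in ", paste(LABELS, collapse = "/"))
  units <- units[order(units$onset), c("onset", "end", "label")]
  rownames(units) <- NULL
  counts <- c(N_tot = nrow(units),
              N_N = sum(units$label == "N"),
              N_Bck = sum(units$label == "Bck"),
              N_DT = sum(units$label == "DT"),
              N_AT = sum(units$label == "AT"),
              N_IE = sum(units$label == "IE"),
              N_X = sum(units$label == "X"))
  structure(list(units = units, counts = counts,
                 ai = asynchrony_index(counts),
                 f_breath = f_breath, duration = duration,
                 warnings = warnings),
            class = "scored_recording")
}

#' @export
print.scored_recording <- function(x, ...) {
  cat("<scored_recording>", x$counts[["N_tot"]], "units over",
      format(x$duration), "s\n")
  print(summarize_counts(x), row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Asynchrony index
#'
#' AI = 100 (N_DT + N_AT + N_IE) / N_tot, in percent, where N_tot counts all
#' units (normal, backup, asynchrony and discarded). Full precision is
#' returned; round to one decimal for display.
#'
#' @param counts Named numeric vector or list with at least \code{N_tot},
#'   \code{N_DT}, \code{N_AT}, \code{N_IE}.
#' @return AI in percent, or NA (empty-score marker) when N_tot is 0.
#' @export
asynchrony_index <- function(counts) {
  counts <- as.list(counts)
  n_tot <- counts$N_tot
  ev <- counts$N_DT + counts$N_AT + counts$N_IE
  if (is.null(n_tot) || is.na(n_tot)) stop("counts must include N_tot")
  if (ev > n_tot) stop("event counts exceed N_tot")
  if (n_tot == 0) return(NA_real_)
  100 * ev / n_tot
}

#' Classify ventilator cycles and efforts into asynchrony events
#'
#' Applies the scoring rules per machine cycle, in priority order:
#' \enumerate{
#'   \item X if the cycle is discarded (leak/turbulence);
#'   \item DT if this rise and the previous rise fall within one inspiratory
#'     effort (the pair forms a single DT unit) — operationally: the
#'     previous cycle was effort-triggered, this rise follows within
#'     \code{dt_max_gap} with no new effort, and the flow evidence supports
#'     a spanning effort (see [dt_vs_atn()]);
#'   \item Bck if no effort lies in the trigger window and the onset is
#'     within \code{bck_tol} of the previous onset + 60/f_bck (the first
#'     cycle of a recording is Bck when effort-free);
#'   \item AT if no effort lies in the trigger window and the rise occurs
#'     during the previous cycle's expiratory phase;
#'   \item N otherwise.
#' }
#' Every unsupported effort outside discarded cycles adds one IE unit at its
#' onset. N_tot counts units, a merged DT pair counting once.
#'
#' @param cycles Cycle table from [segment_cycles()].
#' @param efforts Effort table from [detect_efforts()].
#' @param settings A [ventilator_settings()].
#' @param leaks A [leak_profile()] for the same cycles.
#' @param flow Flow channel (L/min), used for the DT-vs-AT+N flow evidence;
#'   optional (without it the gap + effort-span timing criterion alone is
#'   used).
#' @param rate Sampling rate of \code{flow} in Hz.
#' @param duration Recording duration (s); defaults to the last cycle end.
#' @param params See [detection_params()].
#' @return A [scored_recording()].
#' @export
classify <- function(cycles, efforts, settings, leaks, flow = NULL,
                     rate = NULL, duration = NULL,
                     params = detection_params()) {
  if (!inherits(settings, "ventilator_settings"))
    stop("configuration error: valid ventilator settings required")
  n_cyc <- nrow(cycles)
  if (is.null(duration))
    duration <- if (n_cyc) cycles$end[n_cyc] else 0
  warnings <- character()
  if (n_cyc < 2) warnings <- c(warnings, "insufficient data: fewer than 2 cycles")

  has_effort <- rep(FALSE, n_cyc)
  if (nrow(efforts)) {
    sup <- efforts$cycle_index[efforts$supported]
    has_effort[stats::na.omit(sup)] <- TRUE
  }
  t_bck <- 60 / settings$f_bck
  label <- character(n_cyc)
  pair_with_prev <- logical(n_cyc)

  turb_x <- leaks$turbulence > params$turb_max
  for (i in seq_len(n_cyc)) {
    gap <- if (i > 1) cycles$onset[i] - cycles$onset[i - 1] else Inf
    # A double-trigger pair is considered before the leak discard: the first
    # cycle of a pair is mostly insufflation, so its mean flow exceeds phi_t
    # even without leak; the merged pair spans a complete breath and the
    # leak criterion is re-applied to it.
    dt_candidate <- i > 1 && !pair_with_prev[i - 1] &&
      has_effort[i - 1] && !has_effort[i] &&
      label[i - 1] %in% c("N", "X") && !turb_x[i - 1] && !turb_x[i] &&
      gap <= params$dt_max_gap
    if (dt_candidate) {
      d1 <- cycles$end[i - 1] - cycles$onset[i - 1]
      d2 <- cycles$end[i] - cycles$onset[i]
      # leak reference for the pair: mean flow over the merged (complete)
      # breath, where net patient volume is again ~0
      phi_pair <- (leaks$phi[i - 1] * d1 + leaks$phi[i] * d2) / (d1 + d2)
      verdict <- dt_vs_atn(cycles$onset[i - 1], cycles$onset[i],
                           cycles$insp_end[i - 1], cycles$end[i],
                           flow = flow, rate = rate,
                           leak = phi_pair, params = params)
      if (verdict == "DT") {
        label[i] <- if (phi_pair > params$phi_t) "X" else "DT"
        pair_with_prev[i] <- TRUE
        next
      }
    }
    if (leaks$discarded[i]) { label[i] <- "X"; next }
    if (has_effort[i]) { label[i] <- "N"; next }
    if (i == 1 || abs(gap - t_bck) <= params$bck_tol) {
      label[i] <- "Bck"
    } else if (cycles$onset[i] > cycles$insp_end[i - 1]) {
      label[i] <- "AT"
    } else {
      label[i] <- "N"
    }
  }

  units <- data.frame(onset = numeric(), end = numeric(),
                      label = character())
  i <- 1
  while (i <= n_cyc) {
    if (i < n_cyc && pair_with_prev[i + 1]) {
      units <- rbind(units, data.frame(onset = cycles$onset[i],
                                       end = cycles$end[i + 1],
                                       label = label[i + 1]))
      i <- i + 2
    } else {
      units <- rbind(units, data.frame(onset = cycles$onset[i],
                                       end = cycles$end[i],
                                       label = label[i]))
      i <- i + 1
    }
  }

  if (nrow(efforts)) {
    ie <- efforts[!efforts$supported, , drop = FALSE]
    if (nrow(ie) && any(leaks$discarded)) {
      inside_x <- vapply(ie$onset, function(tt) {
        any(leaks$discarded & cycles$onset <= tt & tt < cycles$end)
      }, logical(1))
      ie <- ie[!inside_x, , drop = FALSE]
    }
    if (nrow(ie))
      units <- rbind(units, data.frame(onset = ie$onset,
                                       end = ie$peak_time +
                                         params$effort_return_window,
                                       label = "IE"))
  }

  f_breath <- if (duration > 0)
    breathing_frequency(efforts, cycles, duration) else NA_real_
  if (!is.na(f_breath) && f_breath > 24)
    warnings <- c(warnings, paste0(
      "breathing frequency ", f_breath,
      "/min exceeds 24/min: auto-triggering may be over-detected"))

  scored_recording(units, duration, f_breath = f_breath,
                   warnings = warnings)
}

#' Discriminate a double-trigger pair from auto-trigger + normal
#'
#' For two machine rises close in time with a single candidate effort
#' spanning them, a DT shows a second inspiratory flow peak much smaller
#' than the first: the lung is still inflated, so the second insufflation
#' draws little or no flow. An auto-trigger following a normal cycle instead
#' starts from a partly deflated lung and reaches an appreciable fraction of
#' the first peak. Without a flow channel only the timing criterion (already
#' satisfied by the caller) is available and DT is returned.
#'
#' @param rise1,rise2 Onset times (s) of the two rises.
#' @param insp_end1 Cycling-off time of the first cycle (s).
#' @param end2 End of the second cycle (s).
#' @param flow Flow channel (L/min) or NULL.
#' @param rate Sampling rate in Hz.
#' @param leak Leak estimate for the pair (L/min), subtracted before
#'   amplitudes are measured.
#' @param params See [detection_params()]; uses \code{ratio_dt}.
#' @return \code{"DT"} or \code{"AT+N"}.
#' @export
dt_vs_atn <- function(rise1, rise2, insp_end1, end2, flow = NULL,
                      rate = NULL, leak = 0,
                      params = detection_params()) {
  if (is.null(flow)) return("DT")
  n <- length(flow)
  win <- function(a, b) {
    i0 <- max(1L, round(a * rate) + 1L); i1 <- min(n, round(b * rate))
    if (i1 < i0) i1 <- i0
    flow[i0:i1] - leak
  }
  peak1 <- max(win(rise1, insp_end1))
  peak2 <- max(win(rise2, min(rise2 + 1.5, end2)))
  if (peak2 < params$ratio_dt * peak1) "DT" else "AT+N"
}

#' Per-recording count summary row
#'
#' One row in the standard reporting schema: N_tot, N_IE, N_AT, N_DT, AI
#' (percent, one decimal), N_Bck, N_X and the breathing frequency.
#'
#' @param scored A [scored_recording()].
#' @return One-row data frame.
#' @export
summarize_counts <- function(scored) {
  cc <- as.list(scored$counts)
  data.frame(N_tot = cc$N_tot, N_IE = cc$N_IE, N_AT = cc$N_AT,
             N_DT = cc$N_DT,
             AI = if (is.na(scored$ai)) NA_real_ else round(scored$ai, 1),
             N_Bck = cc$N_Bck, N_X = cc$N_X,
             f_breath = scored$f_breath)
}

#' Score a recording end to end
#'
#' Convenience wrapper running the full chain on a recording already at the
#' analysis rate: pressure-rise detection, cycle segmentation, leak QC,
#' effort detection and classification.
#'
#' @param rec A \code{waveform_recording} containing pressure and flow.
#' @param settings A [ventilator_settings()].
#' @param params See [detection_params()].
#' @param analysis_rate Rate the classifier operates at (Hz, default 64);
#'   the recording is resampled when it differs.
#' @return A [scored_recording()].
#' @export
score_recording <- function(rec, settings, params = detection_params(),
                            analysis_rate = 64) {
  if (rec$sampling_rate != analysis_rate)
    rec <- resample_recording(rec, analysis_rate)
  rate <- rec$sampling_rate
  p <- rec$channels$pressure
  q <- rec$channels$flow
  onsets <- detect_pressure_rises(p, rate, settings, params)
  if (!length(onsets))
    return(scored_recording(
      data.frame(onset = numeric(), end = numeric(), label = character()),
      rec_duration(rec),
      warnings = "insufficient data: no ventilator cycles detected"))
  insp_ends <- detect_insp_ends(p, rate, onsets, settings, params)
  cycles <- segment_cycles(onsets, insp_ends, rec_duration(rec))
  leaks <- leak_profile(q, rate, cycles, params)
  efforts <- detect_efforts(q, rate, cycles, params)
  classify(cycles, efforts, settings, leaks, flow = q, rate = rate,
           duration = rec_duration(rec), params = params)
}

#' Serialize a scoring to JSON
#'
#' @param scored A [scored_recording()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_scoring <- function(scored, path) {
  obj <- list(duration = scored$duration,
              units = scored$units,
              counts = as.list(scored$counts),
              ai = if (is.na(scored$ai)) NULL else scored$ai,
              f_breath = if (is.na(scored$f_breath)) NULL
                         else scored$f_breath,
              warnings = scored$warnings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a scoring from JSON
#'
#' @param path Path written by [write_scoring()].
#' @return A [scored_recording()].
#' @export
read_scoring <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- as.data.frame(obj$units)
  if (!nrow(units))
    units <- data.frame(onset = numeric(), end = numeric(),
                        label = character())
  scored_recording(units, obj$duration,
                   f_breath = if (is.null(obj$f_breath)) NA_real_
                              else obj$f_breath,
                   warnings = as.character(obj$warnings %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
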