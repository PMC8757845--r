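#' Default detection parameters
#'
#' All tunables of the breath-segmentation and classification chain, with
#' their defaults. Any subset can be overridden by passing a named list to
#' the detection functions.
#'
#' @param ... Named overrides.
#' @return Named list of parameters: \describe{
#'   \item{delta}{Baseline tolerance above EPAP for a rise onset (cmH2O), 1.}
#'   \item{min_rise_frac}{Minimum pressure-rise amplitude as a fraction of
#'     IPAP-EPAP, 0.5.}
#'   \item{refractory}{Minimum separation between rises and between efforts
#'     (s), 0.3.}
#'   \item{cycling_frac}{Pressure fraction of IPAP-EPAP below which the
#'     inspiratory phase is considered over, 0.25.}
#'   \item{trigger_window}{An effort causes a cycle if the cycle onset
#'     follows the effort onset by at most this much (s), 0.3.}
#'   \item{effort_min_amplitude}{Minimum flow deviation above the expiratory
#'     baseline for an effort (L/min), 3.}
#'   \item{effort_smooth_cutoff}{Low-pass cutoff applied to flow before
#'     effort detection (Hz), 2.}
#'   \item{baseline_window}{Running-median window for the expiratory flow
#'     baseline (s), 0.5.}
#'   \item{baseline_lag}{The baseline window ends this far before the
#'     current sample (s), 0.4, so the baseline does not track the effort
#'     transient itself.}
#'   \item{expiratory_guard}{Effort search starts this long after
#'     cycling-off (s), 0.9: the early-expiration flow recovery would
#'     otherwise mimic an inspiratory deflection.}
#'   \item{effort_return_frac}{Fraction of the deviation that must decay
#'     again within \code{effort_return_window} s, 0.3 and 0.7.}
#'   \item{effort_return_window}{See above.}
#'   \item{effort_lag_correction}{Subtracted from flow-derived effort onsets
#'     to compensate the first-order mechanical response lag (s), 0.045.}
#'   \item{bck_tol}{Tolerance on the backup interval for labelling a cycle
#'     Bck (s), 0.15.}
#'   \item{dt_max_gap}{Maximum rise-to-rise gap for a double-trigger pair
#'     (s), 1.5.}
#'   \item{ratio_dt}{Second/first inspiratory flow-peak ratio below which a
#'     candidate pair is a DT, 0.4: a second insufflation into a still
#'     inflated lung draws far less flow than the first, while an
#'     auto-trigger after a normal cycle starts from a partly deflated lung
#'     and exceeds this fraction.}
#'   \item{phi_t}{Leak discard threshold (L/min), 18.}
#'   \item{turb_max}{Turbulence-index discard threshold, 0.4.}}
#' @export
detection_params <- function(...) {
  p <- list(delta = 1, min_rise_frac = 0.5, refractory = 0.3,
            cycling_frac = 0.25, trigger_window = 0.3,
            effort_min_amplitude = 3, effort_smooth_cutoff = 2,
            baseline_window = 0.5, baseline_lag = 0.4,
            expiratory_guard = 0.9, effort_return_frac = 0.3,
            effort_return_window = 0.7, effort_lag_correction = 0.045,
            bck_tol = 0.15, dt_max_gap = 1.5, ratio_dt = 0.4,
            phi_t = 18, turb_max = 0.4)
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)))
    ov <- ov[[1]]
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Detect ventilator pressure rises
#'
#' A rise onset is the last sample at (or below) the EPAP baseline
#' (EPAP + delta) before pressure climbs to at least
#' EPAP + min_rise_frac x (IPAP - EPAP). Consecutive onsets are at least the
#' refractory period apart.
#'
#' @param pressure Airway pressure (cmH2O) at the analysis rate.
#' @param rate Sampling rate in Hz.
#' @param settings A [ventilator_settings()].
#' @param params See [detection_params()].
#' @return Strictly increasing vector of onset times (s).
#' @export
detect_pressure_rises <- function(pressure, rate, settings,
                                  params = detection_params()) {
  if (length(pressure) < 2 * rate)
    stop("insufficient data: pressure channel shorter than 2 s")
  thr_lo <- settings$epap + params$delta
  thr_hi <- settings$epap + params$min_rise_frac *
    (settings$ipap - settings$epap)
  n <- length(pressure)
  cross <- which(pressure[-1] >= thr_hi & pressure[-n] < thr_hi) + 1L
  onsets_idx <- integer(0)
  max_climb <- round(1.5 * rate)
  for (ci in cross) {
    lo <- max(1L, ci - max_climb)
    below <- which(pressure[lo:ci] <= thr_lo)
    if (!length(below)) next
    onsets_idx <- c(onsets_idx, lo + below[length(below)] - 1L)
  }
  onsets_idx <- unique(onsets_idx)
  times <- (onsets_idx - 1) / rate
  keep <- numeric(0)
  for (tt in times)
    if (!length(keep) || tt - keep[length(keep)] >= params$refractory)
      keep <- c(keep, tt)
  keep
}

#' Detect cycling-off (end of insufflation) for each cycle
#'
#' For each onset, the inspiratory phase ends at the first sample after the
#' within-cycle pressure peak where pressure falls below
#' EPAP + cycling_frac x (IPAP - EPAP).
#'
#' @inheritParams detect_pressure_rises
#' @param onsets Onset times from [detect_pressure_rises()].
#' @return Vector of cycling-off times (s), one per onset.
#' @export
detect_insp_ends <- function(pressure, rate, onsets, settings,
                             params = detection_params()) {
  thr <- settings$epap + params$cycling_frac *
    (settings$ipap - settings$epap)
  n <- length(pressure)
  bounds <- c(onsets[-1], n / rate)
  vapply(seq_along(onsets), function(k) {
    i0 <- round(onsets[k] * rate) + 1L
    i1 <- min(n, round(bounds[k] * rate))
    seg <- pressure[i0:i1]
    pk <- which.max(seg)
    below <- which(seg[pk:length(seg)] < thr)
    idx <- if (length(below)) pk + below[1] - 1L else length(seg)
    (i0 + idx - 2) / rate
  }, numeric(1))
}

#' Partition a recording into ventilator cycles
#'
#' Cycle k spans \code{[onset_k, onset_{k+1})}; the last cycle ends at the
#' end of the recording. The union of cycles covers
#' \code{[first onset, record_end)} without overlap.
#'
#' @param onsets Sorted onset times (s).
#' @param insp_ends Cycling-off times, one per onset.
#' @param record_end End of the recording (s).
#' @return Data frame with columns \code{index}, \code{onset},
#'   \code{insp_end}, \code{end}.
#' @export
segment_cycles <- function(onsets, insp_ends, record_end) {
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onsets must be strictly increasing")
  if (!length(onsets))
    return(data.frame(index = integer(), onset = numeric(),
                      insp_end = numeric(), end = numeric()))
  if (length(insp_ends) != length(onsets))
    stop("one insp_end per onset required")
  ends <- c(onsets[-1], record_end)
  insp_ends <- pmin(pmax(insp_ends, onsets + 1e-9), ends - 1e-9)
  data.frame(index = seq_along(onsets), onset = onsets,
             insp_end = insp_ends, end = ends)
}

# Smoothed flow and its lagged running-median baseline deviation (L/min).
effort_deviation <- function(flow, rate, params) {
  wc <- params$effort_smooth_cutoff / (rate / 2)
  s <- mean(flow) + filtfilt_padded(signal::butter(2, wc, "low"),
                                    flow - mean(flow), round(2 * rate))
  k <- round(params$baseline_window * rate)
  if (k %% 2 == 0) k <- k + 1
  med <- stats::runmed(s, k, endrule = "constant")
  lag <- round(params$baseline_lag * rate) + (k - 1) / 2
  baseline <- c(rep(med[1], lag), med[seq_len(length(med) - lag)])
  list(smooth = s, dev = s - baseline)
}

# Find effort bumps in dev over index range [i0, i1]: local maxima with
# prominence and absolute height >= effort_min that decay again.
find_effort_bumps <- function(dev, rate, i0, i1, params) {
  out <- data.frame(onset = numeric(), peak_time = numeric(),
                    amplitude = numeric())
  if (i1 - i0 < 3) return(out)
  seg <- dev[i0:i1]
  m <- length(seg)
  emin <- params$effort_min_amplitude
  locmax <- which(diff(sign(diff(seg))) < 0) + 1L
  last_end <- 1L
  for (p in locmax) {
    if (p <= last_end) next
    if (seg[p] < emin) next
    leftbase <- min(seg[last_end:p])
    prom <- seg[p] - leftbase
    if (prom < emin) next
    ret_end <- min(m, p + round(params$effort_return_window * rate))
    if (min(seg[p:ret_end]) > seg[p] - params$effort_return_frac * prom)
      next
    rise <- which(seg[last_end:p] <= leftbase + 0.1 * prom)
    onset_idx <- last_end + rise[length(rise)] - 1L
    out <- rbind(out, data.frame(
      onset = (i0 + onset_idx - 2) / rate - params$effort_lag_correction,
      peak_time = (i0 + p - 2) / rate,
      amplitude = prom))
    last_end <- p
  }
  out
}

#' Detect patient inspiratory efforts from the flow waveform
#'
#' Efforts appear as transient inspiratory-direction flow deviations above a
#' locally estimated expiratory baseline (a lagged running median of the
#' smoothed flow). Two kinds are returned: \emph{supported} efforts, whose
#' rising edge reaches the detection threshold within the trigger window
#' before a machine cycle onset, and \emph{unsupported} efforts, bumps during
#' an expiratory phase that return toward baseline without a machine
#' response. The early-expiration flow recovery is skipped
#' (\code{expiratory_guard}).
#'
#' @param flow Flow (L/min) at the analysis rate.
#' @param rate Sampling rate in Hz.
#' @param cycles Cycle table from [segment_cycles()].
#' @param params See [detection_params()].
#' @return Data frame with columns \code{onset}, \code{peak_time},
#'   \code{amplitude} (L/min above baseline), \code{supported},
#'   \code{cycle_index} (the triggered cycle for supported efforts, NA
#'   otherwise).
#' @export
detect_efforts <- function(flow, rate, cycles,
                           params = detection_params()) {
  empty <- data.frame(onset = numeric(), peak_time = numeric(),
                      amplitude = numeric(), supported = logical(),
                      cycle_index = integer())
  n <- length(flow)
  ed <- effort_deviation(flow, rate, params)
  dev <- ed$dev
  emin <- params$effort_min_amplitude
  res <- empty

  # supported effort ahead of each cycle onset: at the rise instant the
  # (unsmoothed) flow must already deviate in the inspiratory direction
  # above the expiratory baseline — the patient was pulling when the
  # ventilator fired. The raw signal is used here because zero-phase
  # smoothing spreads the insufflation surge backwards over the window.
  for (k in seq_len(nrow(cycles))) {
    on_idx <- round(cycles$onset[k] * rate) + 1L
    j0 <- max(1L, on_idx - round(0.06 * rate))
    b0 <- max(1L, on_idx - round(0.45 * rate))
    # never span the previous insufflation: the trend is fitted within the
    # current expiratory phase only
    if (k > 1)
      b0 <- max(b0, round(cycles$insp_end[k - 1] * rate) + 3L)
    b1 <- max(b0 + 2L, on_idx - round(0.12 * rate))
    if (on_idx < j0 + 1L || on_idx > n || b1 >= on_idx) next
    # local baseline: linear trend of the raw flow just ahead of the
    # trigger window, extrapolated to the onset. An exponential expiratory
    # recovery is convex, so the extrapolation over-predicts it (never
    # mistaken for an effort), while a true effort jumps far above any
    # local trend.
    xb <- (b0:b1) / rate
    yb <- flow[b0:b1]
    m_j <- mean(flow[j0:on_idx])
    # still descending toward the expiratory trough (e.g. the second rise
    # of a double-trigger pair): frank expiratory flow, no effort
    if (m_j < min(yb)) next
    slope <- stats::cov(xb, yb) / stats::var(xb)
    pred <- mean(yb) + slope * (mean((j0:on_idx) / rate) - mean(xb))
    pre_flow <- m_j - pred
    if (pre_flow < emin) next
    w0 <- max(1L, on_idx - round((params$trigger_window + 0.15) * rate))
    seg <- dev[w0:on_idx]
    base <- which(seg <= 1)
    onset_idx <- if (length(base)) base[length(base)] else 1L
    res <- rbind(res, data.frame(
      onset = max(cycles$onset[k] - params$trigger_window,
                  (w0 + onset_idx - 2) / rate -
                    params$effort_lag_correction),
      peak_time = (w0 + which.max(seg) - 2) / rate,
      amplitude = pre_flow, supported = TRUE, cycle_index = k))
  }

  # unsupported bumps inside each expiratory phase (and before first cycle)
  domains <- list()
  if (nrow(cycles)) {
    domains[[1]] <- c(0, cycles$onset[1] - params$trigger_window - 0.1)
    for (k in seq_len(nrow(cycles))) {
      hi <- cycles$end[k] -
        if (k < nrow(cycles)) params$trigger_window + 0.1 else 0
      domains[[k + 1]] <- c(cycles$insp_end[k] + params$expiratory_guard, hi)
    }
  } else domains[[1]] <- c(0, n / rate)
  for (d in domains) {
    i0 <- max(1L, round(d[1] * rate) + 1L)
    i1 <- min(n, round(d[2] * rate))
    bump <- find_effort_bumps(dev, rate, i0, i1, params)
    if (nrow(bump))
      res <- rbind(res, data.frame(bump, supported = FALSE,
                                   cycle_index = NA_integer_))
  }

  if (!nrow(res)) return(empty)
  res <- res[order(res$onset), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  last <- res$onset[1]
  for (i in seq_len(nrow(res))[-1]) {
    if (res$onset[i] - last < params$refractory) keep[i] <- FALSE
    else last <- res$onset[i]
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Breathing frequency
#'
#' Patient breaths are the distinct inspiratory efforts plus the effort-free
#' machine cycles (backup or auto-triggered cycles still inflate the
#' patient). Reported in breaths/min, rounded to the nearest integer.
#'
#' @param efforts Effort table from [detect_efforts()].
#' @param cycles Cycle table from [segment_cycles()].
#' @param duration Recording duration in seconds (> 0).
#' @return Breaths per minute (integer).
#' @export
breathing_frequency <- function(efforts, cycles, duration) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  n_eff <- if (is.null(efforts)) 0L else nrow(efforts)
  n_cyc <- if (is.null(cycles)) 0L else nrow(cycles)
  n_supported_cycles <- if (n_eff)
    length(unique(stats::na.omit(efforts$cycle_index))) else 0L
  breaths <- n_eff + (n_cyc - n_supported_cycles)
  round(breaths / duration * 60)
}
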