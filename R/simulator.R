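#' Define a synthetic pressure-support-ventilation scenario
#'
#' A scenario fully determines one synthetic recording: the ventilator
#' settings and controller parameters, single-compartment respiratory
#' mechanics, a train of patient inspiratory efforts (raised-cosine
#' muscle-pressure pulses), scheduled auto-trigger instants, a leak profile
#' (constant plus bursts), optional high-frequency turbulence bursts, and
#' per-channel measurement noise. The seed fixes all randomness.
#'
#' The ventilator triggers when the effort-driven flow component exceeds
#' \code{trigger_sensitivity}; it pressurizes from EPAP toward IPAP with an
#' exponential rise, and cycles off to expiration when inspiratory flow falls
#' below \code{cycle_off_frac} of the cycle's peak flow. If no trigger occurs
#' within 60/f_bck s of the previous onset, a backup cycle is delivered.
#'
#' @param duration Recording length in seconds.
#' @param settings A [ventilator_settings()] object.
#' @param resistance Airway resistance in cmH2O/(L/s) (default 10).
#' @param compliance Respiratory-system compliance in L/cmH2O (default 0.05;
#'   use ~0.03 for a restrictive profile).
#' @param efforts Data frame with columns \code{onset} (s), \code{amplitude}
#'   (cmH2O of muscle pressure) and \code{duration} (s); may have zero rows.
#' @param auto_trigger_times Times (s) at which a machine rise is forced with
#'   no underlying effort (auto-triggering).
#' @param trigger_sensitivity Trigger threshold on effort-driven flow, L/min
#'   (default 15; efforts whose peak effort flow stays below it are
#'   ineffective).
#' @param rise_time Pressurization time constant x3 (s to ~95% of IPAP),
#'   default 0.15.
#' @param cycle_off_frac Expiratory cycling threshold as a fraction of peak
#'   inspiratory flow (default 0.25).
#' @param leak_constant Constant leak in L/min added to the measured flow.
#' @param leak_bursts Data frame with columns \code{onset}, \code{duration}
#'   (s) and \code{magnitude} (L/min): raised-cosine leak transients.
#' @param turbulence Data frame with columns \code{onset}, \code{duration}
#'   (s) and \code{amplitude} (L/min): 10 Hz oscillation bursts that emulate
#'   turbulent flow (exercises the discard rule).
#' @param noise_sd Named vector of measurement-noise standard deviations:
#'   \code{pressure} (cmH2O), \code{flow} (L/min), \code{belt} (a.u.).
#' @param seed Integer seed fixing the noise and belt drift.
#' @param acquisition_rate Integration/acquisition rate in Hz (default 1000).
#' @return An object of class \code{psv_scenario}.
#' @export
psv_scenario <- function(duration, settings,
                         resistance = 10, compliance = 0.05,
                         efforts = NULL,
                         auto_trigger_times = numeric(),
                         trigger_sensitivity = 15,
                         rise_time = 0.15,
                         cycle_off_frac = 0.25,
                         leak_constant = 0,
                         leak_bursts = NULL,
                         turbulence = NULL,
                         noise_sd = c(pressure = 0, flow = 0, belt = 0),
                         seed = 1L,
                         acquisition_rate = 1000) {
  stopifnot(inherits(settings, "ventilator_settings"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (resistance <= 0 || compliance <= 0)
    stop("mechanics parameters must be positive")
  if (rise_time >= 60 / settings$f_bck)
    stop("scenario error: rise time must be shorter than the backup period")
  if (is.null(efforts))
    efforts <- data.frame(onset = numeric(), amplitude = numeric(),
                          duration = numeric())
  efforts <- efforts[order(efforts$onset), , drop = FALSE]
  if (nrow(efforts) && (any(efforts$amplitude <= 0) |
                        any(efforts$duration <= 0)))
    stop("scenario error: effort amplitudes and durations must be positive")
  nz <- c(pressure = 0, flow = 0, belt = 0)
  nz[names(noise_sd)] <- noise_sd
  structure(list(duration = duration, settings = settings,
                 resistance = resistance, compliance = compliance,
                 efforts = efforts,
                 auto_trigger_times = sort(auto_trigger_times),
                 trigger_sensitivity = trigger_sensitivity,
                 rise_time = rise_time, cycle_off_frac = cycle_off_frac,
                 leak_constant = leak_constant,
                 leak_bursts = leak_bursts, turbulence = turbulence,
                 noise_sd = nz, seed = as.integer(seed),
                 acquisition_rate = acquisition_rate),
            class = "psv_scenario")
}

# Raised-cosine pulse train evaluated on a time grid.
raised_cosine_train <- function(t, onset, amplitude, duration) {
  out <- numeric(length(t))
  for (k in seq_along(onset)) {
    idx <- which(t >= onset[k] & t < onset[k] + duration[k])
    ph <- (t[idx] - onset[k]) / duration[k]
    out[idx] <- out[idx] + amplitude[k] / 2 * (1 - cos(2 * pi * ph))
  }
  out
}

#' Simulate a PSV recording with ground truth
#'
#' Integrates the ventilator controller and the single-compartment equation
#' of motion at the acquisition rate, adds leak, turbulence, belt and noise
#' channels, resamples to the analysis rate through the same band-limited
#' path used for real recordings, and returns the recording together with
#' exact ground-truth annotations: every machine cycle's cause (triggered /
#' backup / auto / re-trigger within one effort = double-trigger pair) and
#' every non-triggering effort as an ineffective effort (IE).
#'
#' @param scenario A [psv_scenario()].
#' @param analysis_rate Output rate in Hz (default 64).
#' @return List with elements \code{recording} (a
#'   \code{waveform_recording} at \code{analysis_rate}), \code{truth} (a
#'   \code{scored_recording} built from the ground truth) and \code{cycles}
#'   (data frame of machine cycles with onset, insp_end, cause, effort id).
#' @export
simulate_psv <- function(scenario, analysis_rate = 64) {
  sc <- scenario
  fs <- sc$acquisition_rate
  n <- round(sc$duration * fs)
  t <- (seq_len(n) - 1) / fs
  ef <- sc$efforts
  pmus <- raised_cosine_train(t, ef$onset, ef$amplitude, ef$duration)

  core <- psv_simulate_core(
    pmus, 1 / fs, sc$settings$epap, sc$settings$ipap, sc$settings$f_bck,
    ef$onset, ef$onset + ef$duration, sc$auto_trigger_times,
    sc$trigger_sensitivity / 60, sc$rise_time / 3, 0.08,
    sc$cycle_off_frac, 0.3, 3.0, 0.3, sc$resistance, sc$compliance)

  leak <- rep(sc$leak_constant, n)
  if (!is.null(sc$leak_bursts) && nrow(sc$leak_bursts))
    leak <- leak + raised_cosine_train(t, sc$leak_bursts$onset,
                                       sc$leak_bursts$magnitude,
                                       sc$leak_bursts$duration)
  turb <- numeric(n)
  if (!is.null(sc$turbulence) && nrow(sc$turbulence)) {
    env <- raised_cosine_train(t, sc$turbulence$onset,
                               sc$turbulence$amplitude,
                               sc$turbulence$duration)
    turb <- env * sin(2 * pi * 10 * t)
  }

  set.seed(sc$seed)
  vol <- core$vol - sc$compliance * sc$settings$epap  # volume above baseline
  drift_th <- 0.3 * sin(2 * pi * t / 97 + stats::runif(1, 0, 2 * pi))
  drift_ab <- 0.3 * sin(2 * pi * t / 131 + stats::runif(1, 0, 2 * pi))
  pressure <- core$paw + stats::rnorm(n, 0, sc$noise_sd[["pressure"]])
  flow <- core$qpat * 60 + leak + turb +
    stats::rnorm(n, 0, sc$noise_sd[["flow"]])
  belt_th <- 0.6 * vol + drift_th + stats::rnorm(n, 0, sc$noise_sd[["belt"]])
  belt_ab <- 0.4 * vol + drift_ab + stats::rnorm(n, 0, sc$noise_sd[["belt"]])

  rec <- waveform_recording(list(pressure = pressure, flow = flow,
                                 belt_thorax = belt_th,
                                 belt_abdomen = belt_ab), fs)
  if (analysis_rate != fs) rec <- resample_recording(rec, analysis_rate)

  cycles <- data.frame(onset = core$onset, insp_end = core$insp_end,
                       cause = c("triggered", "backup", "auto")[core$cause + 1],
                       effort_id = core$effort_id + 1L)
  cycles$effort_id[cycles$effort_id == 0L] <- NA_integer_

  truth <- ground_truth_scoring(cycles, ef, sc$duration)
  list(recording = rec, truth = truth, cycles = cycles)
}

# Build a scored_recording from simulator cycle causes and the effort train.
ground_truth_scoring <- function(cycles, efforts, duration) {
  n_cyc <- nrow(cycles)
  label <- character(n_cyc)
  pair_with_prev <- logical(n_cyc)
  for (i in seq_len(n_cyc)) {
    label[i] <- switch(cycles$cause[i], triggered = "N", backup = "Bck",
                       auto = "AT")
    if (i > 1 && cycles$cause[i] == "triggered" &&
        !is.na(cycles$effort_id[i]) &&
        !is.na(cycles$effort_id[i - 1]) &&
        cycles$effort_id[i] == cycles$effort_id[i - 1] &&
        !pair_with_prev[i - 1]) {
      pair_with_prev[i] <- TRUE
    }
  }
  ends <- c(cycles$onset[-1], duration)
  units <- data.frame(onset = numeric(), end = numeric(),
                      label = character())
  i <- 1
  while (i <= n_cyc) {
    if (i < n_cyc && pair_with_prev[i + 1]) {
      units <- rbind(units, data.frame(onset = cycles$onset[i],
                                       end = ends[i + 1], label = "DT"))
      i <- i + 2
    } else {
      units <- rbind(units, data.frame(onset = cycles$onset[i],
                                       end = ends[i], label = label[i]))
      i <- i + 1
    }
  }
  triggered_efforts <- stats::na.omit(cycles$effort_id)
  if (nrow(efforts)) {
    ie_ids <- setdiff(seq_len(nrow(efforts)), triggered_efforts)
    if (length(ie_ids))
      units <- rbind(units,
                     data.frame(onset = efforts$onset[ie_ids],
                                end = efforts$onset[ie_ids] +
                                  efforts$duration[ie_ids],
                                label = "IE"))
  }
  units <- units[order(units$onset), , drop = FALSE]
  rownames(units) <- NULL
  scored_recording(units, duration)
}

#' Inject asynchrony events into a scenario
#'
#' Adds ground-truth-controlled events: \code{IE} adds a sub-threshold
#' effort (too weak to trigger) at the given time; \code{AT} schedules a
#' spontaneous machine rise with no effort; \code{DT} adds a long, strong
#' effort that outlasts the first cycle's cycling-off and re-triggers the
#' ventilator.
#'
#' @param scenario A [psv_scenario()].
#' @param events Data frame with columns \code{type} (one of "IE", "AT",
#'   "DT") and \code{time} (s). Event times must lie inside the scenario
#'   duration and be separated by at least 1 s from each other.
#' @param ie_amplitude Muscle pressure of injected IE efforts in cmH2O
#'   (default 2, below the default trigger threshold).
#' @param ie_duration Duration of injected IE efforts in s (default 0.8).
#' @param dt_amplitude Muscle pressure of injected DT efforts (default 15).
#' @param dt_duration Duration of injected DT efforts in s (default 1.7).
#' @return The modified scenario.
#' @export
inject_events <- function(scenario, events, ie_amplitude = 2,
                          ie_duration = 0.8, dt_amplitude = 15,
                          dt_duration = 1.7) {
  stopifnot(inherits(scenario, "psv_scenario"))
  if (!all(events$type %in% c("IE", "AT", "DT")))
    stop("scenario error: event types must be IE, AT or DT")
  if (any(events$time <= 0 | events$time >= scenario$duration))
    stop("scenario error: event times must lie inside the duration")
  tt <- sort(events$time)
  if (length(tt) > 1 && min(diff(tt)) < 1)
    stop("scenario error: conflicting events (separation < 1 s)")
  sc <- scenario
  for (k in seq_len(nrow(events))) {
    ty <- events$type[k]; tm <- events$time[k]
    if (ty == "IE") {
      sc$efforts <- rbind(sc$efforts,
                          data.frame(onset = tm, amplitude = ie_amplitude,
                                     duration = ie_duration))
    } else if (ty == "AT") {
      sc$auto_trigger_times <- sort(c(sc$auto_trigger_times, tm))
    } else {
      sc$efforts <- rbind(sc$efforts,
                          data.frame(onset = tm, amplitude = dt_amplitude,
                                     duration = dt_duration))
    }
  }
  sc$efforts <- sc$efforts[order(sc$efforts$onset), , drop = FALSE]
  sc
}

#' Write a simulated fixture to disk
#'
#' Writes the waveform as delimited text (round-trips with
#' [read_recording()]) and the ground truth as JSON.
#'
#' @param recording A \code{waveform_recording}.
#' @param truth A \code{scored_recording} (the ground truth).
#' @param dir Output directory (created if missing).
#' @param stem File stem (default "fixture").
#' @return Named character vector of the two paths.
#' @export
write_fixture <- function(recording, truth, dir, stem = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wf <- file.path(dir, paste0(stem, ".txt"))
  gt <- file.path(dir, paste0(stem, "_truth.json"))
  write_recording(recording, wf)
  write_scoring(truth, gt)
  c(waveform = wf, truth = gt)
}
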