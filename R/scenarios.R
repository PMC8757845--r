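#' Standard simulation scenarios
#'
#' Convenience constructors for the study conditions used throughout the
#' test-suite and validation runs: 20-min pressure-support recordings with a
#' backup frequency, a regular spontaneous breathing pattern, and optional
#' injected asynchrony events with exact ground truth.
#'
#' \code{scenario_backup_only} has no patient activity: every cycle is a
#' backup cycle at exactly 60/f_bck s. \code{scenario_regular_breathing}
#' adds an effort train at a fixed breath period (default 4 s, i.e. 15
#' breaths/min, all triggering). \code{scenario_with_events} injects
#' \code{n_ie} ineffective efforts, \code{n_at} auto-triggers and
#' \code{n_dt} double-triggers into randomly chosen, well-separated breaths
#' (seeded).
#'
#' @param duration Length in seconds (default 1200, a 20-min session).
#' @param settings [ventilator_settings()] (default EPAP 4, IPAP 16,
#'   f_bck 12).
#' @param seed Integer seed.
#' @param breath_period Seconds between effort onsets (default 4).
#' @param effort_amplitude Muscle pressure of regular efforts, cmH2O
#'   (default 8).
#' @param effort_duration Duration of regular efforts, s (default 0.8).
#' @param n_ie,n_at,n_dt Number of injected events by type.
#' @param n_bck Number of single-breath pauses (one regular effort removed,
#'   so one backup cycle is delivered).
#' @param noise_flow,noise_pressure Measurement noise SD (L/min, cmH2O).
#' @param leak_constant Constant leak in L/min.
#' @param ... Passed through to [psv_scenario()].
#' @return A [psv_scenario()].
#' @export
scenario_backup_only <- function(duration = 1200,
                                 settings = ventilator_settings(4, 16, 12),
                                 seed = 1L, ...) {
  psv_scenario(duration, settings, seed = seed, ...)
}

#' @rdname scenario_backup_only
#' @export
scenario_regular_breathing <- function(duration = 1200,
                                       settings = ventilator_settings(4, 16, 12),
                                       breath_period = 4,
                                       effort_amplitude = 8,
                                       effort_duration = 0.8,
                                       seed = 1L, ...) {
  onsets <- seq(2, duration - 2, by = breath_period)
  efforts <- data.frame(onset = onsets, amplitude = effort_amplitude,
                        duration = effort_duration)
  psv_scenario(duration, settings, efforts = efforts, seed = seed, ...)
}

#' @rdname scenario_backup_only
#' @export
scenario_with_events <- function(duration = 1200,
                                 settings = ventilator_settings(4, 16, 12),
                                 n_ie = 15, n_at = 0, n_dt = 0, n_bck = 0,
                                 breath_period = 4,
                                 effort_amplitude = 8,
                                 effort_duration = 0.8,
                                 noise_flow = 0, noise_pressure = 0,
                                 leak_constant = 0, seed = 1L, ...) {
  sc <- scenario_regular_breathing(
    duration, settings, breath_period, effort_amplitude, effort_duration,
    seed = seed, leak_constant = leak_constant,
    noise_sd = c(pressure = noise_pressure, flow = noise_flow, belt = 0.05),
    ...)
  n_ev <- n_ie + n_at + n_dt + n_bck
  if (n_ev == 0) return(sc)
  n_breaths <- nrow(sc$efforts)
  # candidate breaths: interior, and keep one untouched breath between any
  # two event slots so events never interact
  candidates <- seq(3, n_breaths - 3)
  set.seed(seed)
  slots <- integer(0)
  pool <- candidates
  while (length(slots) < n_ev && length(pool)) {
    pick <- if (length(pool) == 1) pool else sample(pool, 1)
    slots <- c(slots, pick)
    pool <- setdiff(pool, (pick - 1):(pick + 1))
  }
  if (length(slots) < n_ev)
    stop("scenario error: not enough breaths to place all events")
  types <- rep(c("IE", "AT", "DT", "Bck"), c(n_ie, n_at, n_dt, n_bck))
  base <- sc$efforts$onset[slots]
  # IE: late expiration (clear of the post-insufflation flow recovery);
  # AT: expiration, with the following effort postponed so it rises out of
  # quiet late expiration rather than the recovery after the auto-trigger
  ev <- data.frame(type = types,
                   time = ifelse(types == "IE", base + 3.0,
                          ifelse(types == "AT", base + 2.3, base)))
  at_slots <- slots[types == "AT"]
  if (length(at_slots)) {
    nxt <- match(sc$efforts$onset[at_slots] + breath_period,
                 sc$efforts$onset)
    nxt <- nxt[!is.na(nxt)]
    sc$efforts$onset[nxt] <- sc$efforts$onset[nxt] + 1.3
  }
  drop_slots <- slots[types %in% c("DT", "Bck")]
  if (length(drop_slots)) {
    # a DT event replaces its breath's regular effort; a Bck pause removes it
    sc$efforts <- sc$efforts[-drop_slots, , drop = FALSE]
  }
  ev <- ev[ev$type != "Bck", , drop = FALSE]
  if (nrow(ev)) sc <- inject_events(sc, ev[order(ev$time), , drop = FALSE])
  sc$seed <- as.integer(seed)
  sc
}
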