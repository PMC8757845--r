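#' Per-cycle leakage
#'
#' The leakage attributed to one ventilatory cycle is the time average of the
#' total circuit flow over the cycle,
#' \deqn{\Phi = \frac{1}{t_{end}-t_{init}} \int_{t_{init}}^{t_{end}} Q(t)\,dt,}
#' computed by trapezoidal integration on the sample grid. Because the net
#' patient volume over a complete breath is approximately zero, the mean
#' total flow estimates the mask/circuit leak; no inspiratory/expiratory
#' split is attempted. The value is constant over the cycle.
#'
#' @param flow Flow channel (L/min).
#' @param rate Sampling rate in Hz.
#' @param t_init Cycle start (s).
#' @param t_end Cycle end (s); must exceed \code{t_init}.
#' @return Leak in L/min.
#' @export
cycle_leak <- function(flow, rate, t_init, t_end) {
  if (t_end <= t_init) stop("t_end must exceed t_init")
  n <- length(flow)
  i0 <- max(1L, round(t_init * rate) + 1L)
  i1 <- min(n, round(t_end * rate) + 1L)
  if (i1 <= i0) stop("cycle contains fewer than two samples")
  tt <- (seq(i0, i1) - 1) / rate
  pracma::trapz(tt, flow[i0:i1]) / (tt[length(tt)] - tt[1])
}

#' Leak profile and discard flags for a segmented recording
#'
#' Computes the per-cycle leak and flags cycles for discarding (label X)
#' when the leak exceeds the threshold \code{phi_t} \emph{or} the cycle is
#' excessively turbulent. The turbulence index is the RMS of the flow
#' component above 5 Hz within the cycle, normalized by the RMS of the
#' breathing-band (below 5 Hz, mean-removed) component; cycles with
#' index > \code{turb_max} are discarded. Discarded cycles are excluded from classification but still
#' counted in N_tot.
#'
#' @param flow Flow channel (L/min).
#' @param rate Sampling rate in Hz.
#' @param cycles Cycle table from [segment_cycles()].
#' @param params See [detection_params()]; uses \code{phi_t} (default 18
#'   L/min) and \code{turb_max} (default 0.4).
#' @return An object of class \code{leak_profile}: data frame with columns
#'   \code{index}, \code{phi} (L/min), \code{turbulence}, \code{discarded},
#'   with the threshold stored in \code{attr(, "phi_t")}.
#' @export
leak_profile <- function(flow, rate, cycles, params = detection_params()) {
  n_cyc <- nrow(cycles)
  phi <- turb <- numeric(n_cyc)
  if (n_cyc) {
    hf <- filtfilt_padded(signal::butter(4, 5 / (rate / 2), "high"),
                          flow - mean(flow), round(2 * rate))
    lf <- flow - mean(flow) - hf
    for (k in seq_len(n_cyc)) {
      phi[k] <- cycle_leak(flow, rate, cycles$onset[k], cycles$end[k])
      i0 <- round(cycles$onset[k] * rate) + 1L
      i1 <- min(length(flow), round(cycles$end[k] * rate))
      seg <- lf[i0:i1]
      denom <- sqrt(mean((seg - mean(seg))^2))
      turb[k] <- if (denom > 0) sqrt(mean(hf[i0:i1]^2)) / denom else 0
    }
  }
  out <- data.frame(index = cycles$index, phi = phi, turbulence = turb)
  out$discarded <- flag_discarded(phi, turb, params)
  attr(out, "phi_t") <- params$phi_t
  class(out) <- c("leak_profile", "data.frame")
  out
}

#' Discard rule
#'
#' A cycle is discarded when its leak exceeds \code{phi_t} or its turbulence
#' index exceeds \code{turb_max} (either criterion suffices).
#'
#' @param phi Per-cycle leak values (L/min).
#' @param turbulence Per-cycle turbulence indices (same length); defaults to
#'   zero (leak criterion only).
#' @param params See [detection_params()].
#' @return Logical vector of discard flags.
#' @export
flag_discarded <- function(phi, turbulence = rep(0, length(phi)),
                           params = detection_params()) {
  phi > params$phi_t | turbulence > params$turb_max
}
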