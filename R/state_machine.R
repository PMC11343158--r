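# Per-attempt patch-clamp stage rules as pure decision functions over
# resistance / current measurements. These are the thresholds an automated
# patcher applies at each stage of an attempt: neuron hunting, gigasealing,
# break-in, and recording quality control. The simulator reuses them and they
# are testable on synthetic traces from the fixtures module.

#' Construct a neuron-hunting trace
#'
#' During neuron hunting the pipette descends in 0.1 um steps while tip
#' resistance is monitored; a sustained resistance rise signals cell contact.
#'
#' @param positions_um Strictly decreasing pipette depths (um), one per step.
#' @param resistances_mohm Positive tip resistances (MOhm), one per step.
#' @return A `hunt_trace` object (data frame with columns `position_um`,
#'   `resistance_mohm`).
#' @export
hunt_trace <- function(positions_um, resistances_mohm) {
  if (length(positions_um) != length(resistances_mohm)) {
    stop_domain("positions and resistances must have equal length")
  }
  if (length(positions_um) > 1 && any(diff(positions_um) >= 0)) {
    stop_domain("`positions_um` must be strictly decreasing (descending steps)")
  }
  if (any(resistances_mohm <= 0)) {
    stop_domain("`resistances_mohm` must be positive")
  }
  structure(
    data.frame(position_um = positions_um, resistance_mohm = resistances_mohm),
    class = c("hunt_trace", "data.frame")
  )
}

#' Detect a neuron in a hunting trace
#'
#' A neuron is detected when the pipette resistance increases by at least
#' `threshold_mohm` over a window of `window_steps` consecutive descending
#' steps, evaluated as the difference between the window's last and first
#' resistance. Returns the 1-based index of the first step at which the
#' criterion fires, or `NA` if no window qualifies (including traces shorter
#' than the window).
#'
#' @param trace A [hunt_trace()] (or data frame with a `resistance_mohm`
#'   column).
#' @param threshold_mohm Resistance rise required (MOhm); default 0.2.
#' @param window_steps Window length in steps; default 5.
#' @return Integer detection index, or `NA_integer_`.
#' @export
detect_neuron <- function(trace, threshold_mohm = 0.2, window_steps = 5L) {
  r <- trace$resistance_mohm
  n <- length(r)
  if (n < window_steps) return(NA_integer_)
  for (i in seq.int(window_steps, n)) {
    if (r[i] - r[i - window_steps + 1L] >= threshold_mohm) return(as.integer(i))
  }
  NA_integer_
}

#' Has a gigaseal formed?
#'
#' A gigaseal is declared once the measured seal resistance reaches 1 GOhm
#' (1000 MOhm, inclusive). The controller then waits `wait_s` seconds before
#' proceeding to break-in; the wait is reported for callers that schedule the
#' transition.
#'
#' @param resistance_mohm Seal resistance (MOhm).
#' @param threshold_mohm Gigaseal threshold; default 1000 MOhm.
#' @param wait_s Post-gigaseal settling wait before break-in; default 5 s.
#' @return Logical; attribute `wait_s` carries the settling time.
#' @export
gigaseal_reached <- function(resistance_mohm, threshold_mohm = 1000, wait_s = 5) {
  out <- resistance_mohm >= threshold_mohm
  attr(out, "wait_s") <- wait_s
  out
}

#' Was a break-in attempt successful?
#'
#' Break-in (membrane rupture by suction pulses of 100-1000 ms at -345 mBar)
#' succeeds when the measured resistance drops strictly below 800 MOhm while
#' the holding current at -70 mV remains low, i.e. not more negative than
#' -200 pA.
#'
#' @param resistance_mohm Post-suction resistance (MOhm).
#' @param holding_current_pa Holding current at -70 mV (pA; negative inward).
#' @param resistance_limit_mohm Upper resistance bound; default 800.
#' @param current_floor_pa Most negative acceptable holding current; default
#'   -200.
#' @return Logical.
#' @export
break_in_success <- function(resistance_mohm, holding_current_pa,
                             resistance_limit_mohm = 800,
                             current_floor_pa = -200) {
  resistance_mohm < resistance_limit_mohm & holding_current_pa >= current_floor_pa
}

#' Evaluate recording quality from an access-resistance series
#'
#' Whole-cell recordings are judged on access (series) resistance over time:
#' all values below 40 MOhm -> `"include"` in analysis; any value above
#' 50 MOhm -> `"stop"` recording (earlier data kept); values in the 40-50
#' MOhm band indicate degraded seal quality and by default the cell is
#' `"exclude"`d from analysis while recording continues (`band_action`
#' configurable).
#'
#' @param access_mohm Numeric series of access resistances (MOhm), non-empty.
#' @param include_below_mohm Inclusion ceiling; default 40.
#' @param stop_above_mohm Stop-recording threshold; default 50.
#' @param band_action Verdict for the in-between band: `"exclude"` (default)
#'   or `"stop"`.
#' @return One of `"include"`, `"exclude"`, `"stop"`.
#' @export
qc_evaluate <- function(access_mohm, include_below_mohm = 40,
                        stop_above_mohm = 50,
                        band_action = c("exclude", "stop")) {
  band_action <- match.arg(band_action)
  if (length(access_mohm) == 0L) stop_domain("`access_mohm` must be non-empty")
  if (any(access_mohm > stop_above_mohm)) return("stop")
  if (any(access_mohm >= include_below_mohm)) return(band_action)
  "include"
}

#' Build a current-clamp stimulus protocol
#'
#' Two protocols used once a whole-cell recording is established, returned as
#' sample-exact waveforms at `sample_rate_hz`:
#'
#' * `"whole_cell_check"`: 1 s at 0 pA, 1 s at `step_pa`, 1 s at 0 pA
#'   (3 s total). The step amplitude is swept from -300 to +300 pA in
#'   practice; `step_pa` selects one sweep.
#' * `"fi_curve"`: a family of 16 sweeps with 3 s pulses from -20 to +280 pA
#'   in 20 pA steps, each preceded by a 2 s, -20 pA hyperpolarizing step that
#'   ends 500 ms before pulse onset.
#'
#' @param kind `"whole_cell_check"` or `"fi_curve"`.
#' @param step_pa Step amplitude (pA) for `whole_cell_check`; default 300.
#' @param sample_rate_hz Sampling rate; default 10000.
#' @return A data frame with columns `sweep` (integer), `amplitude_pa` (the
#'   sweep's pulse amplitude), `time_s`, `current_pa`.
#' @export
build_current_clamp_protocol <- function(kind = c("whole_cell_check", "fi_curve"),
                                         step_pa = 300,
                                         sample_rate_hz = 10000) {
  kind <- match.arg(kind)
  dt <- 1 / sample_rate_hz
  if (kind == "whole_cell_check") {
    tt <- seq(0, 3 - dt, by = dt)
    cur <- ifelse(tt >= 1 & tt < 2, step_pa, 0)
    return(data.frame(sweep = 1L, amplitude_pa = step_pa, time_s = tt,
                      current_pa = cur))
  }
  # fi_curve: -20 pA for 2 s, 0 pA for 0.5 s, pulse for 3 s, 0 pA for 0.5 s
  amps <- seq(-20, 280, by = 20)
  tt <- seq(0, 6 - dt, by = dt)
  hyper <- tt < 2
  pulse <- tt >= 2.5 & tt < 5.5
  out <- lapply(seq_along(amps), function(i) {
    cur <- numeric(length(tt))
    cur[hyper] <- -20
    cur[pulse] <- amps[i]
    data.frame(sweep = i, amplitude_pa = amps[i], time_s = tt, current_pa = cur)
  })
  do.call(rbind, out)
}
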