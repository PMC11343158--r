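# Bidirectional connectivity-test recordings: presynaptic spike trains,
# synthetic postsynaptic current sweeps, sweep averaging, and evoked-response
# classification.
#
# Screening protocol: the presynaptic cell is driven in current clamp to fire
# a short spike train (default five action potentials at 20 Hz) while the
# postsynaptic candidate is voltage clamped at -70 mV and its currents
# recorded; the test is then repeated with roles swapped. Sweeps are averaged
# (default three) before evoked-response detection.

#' Build a presynaptic stimulus spike train
#'
#' Spike times are equally spaced at `1000 / rate_hz` ms starting at 0
#' (relative to stimulus onset).
#'
#' @param n_spikes Number of action potentials; default 5.
#' @param rate_hz Spike rate; default 20 Hz.
#' @return A `stim_train` object: list with `spike_times_ms`, `n_spikes`,
#'   `rate_hz`.
#' @examples
#' build_stim_train()  # spikes at 0, 50, 100, 150, 200 ms
#' @export
build_stim_train <- function(n_spikes = 5L, rate_hz = 20) {
  n_spikes <- check_count(n_spikes, "n_spikes", min = 1L)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop_domain("`rate_hz` must be a positive number")
  }
  structure(
    list(
      spike_times_ms = (seq_len(n_spikes) - 1) * 1000 / rate_hz,
      n_spikes = n_spikes, rate_hz = as.numeric(rate_hz)
    ),
    class = "stim_train"
  )
}

# PSC kernel: difference of exponentials on the sweep's time grid, normalized
# so its sampled peak is exactly 1. Returned as a function of (t - onset) ms.
psc_kernel <- function(t_ms, rise_ms, decay_ms) {
  if (rise_ms <= 0 || decay_ms <= rise_ms) {
    stop_domain("require 0 < rise_ms < decay_ms")
  }
  g <- ifelse(t_ms < 0, 0, exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms))
  mx <- max(g)
  if (mx > 0) g / mx else g
}

#' Synthesize a postsynaptic current sweep
#'
#' Generates one voltage-clamp sweep (-70 mV holding) as baseline 0 pA plus
#' Gaussian noise; if `connected`, an inward (negative) difference-of-
#' exponentials current of peak `psc_amplitude_pa` is added `latency_ms`
#' after each presynaptic spike. The stimulus train starts `stim_onset_ms`
#' into the sweep so a pre-stimulus baseline window exists. Deterministic
#' under `seed`.
#'
#' @param train A [build_stim_train()] object.
#' @param connected Logical: does a synaptic connection exist?
#' @param psc_amplitude_pa Peak evoked current magnitude (pA); default 50.
#' @param rise_ms,decay_ms PSC kernel time constants; defaults 1 and 10 ms.
#' @param latency_ms Synaptic latency after each spike; default 2 ms.
#' @param noise_sd_pa Gaussian noise SD (pA); default 5.
#' @param stim_onset_ms Time of the first spike within the sweep; default 50.
#' @param duration_ms Sweep length; default 500 ms.
#' @param sample_rate_hz Sampling rate; default 10000.
#' @param seed Optional integer seed for the noise draw.
#' @return A `screen_sweep`: data frame with columns `time_ms`,
#'   `current_pa`; attributes `stim_onset_ms` and `sample_rate_hz`.
#' @export
synthesize_sweep <- function(train, connected,
                             psc_amplitude_pa = 50,
                             rise_ms = 1, decay_ms = 10, latency_ms = 2,
                             noise_sd_pa = 5,
                             stim_onset_ms = 50, duration_ms = 500,
                             sample_rate_hz = 10000, seed = NULL) {
  if (noise_sd_pa < 0) stop_domain("`noise_sd_pa` must be >= 0")
  dt <- 1000 / sample_rate_hz
  t_ms <- seq(0, duration_ms - dt, by = dt)
  cur <- numeric(length(t_ms))
  if (isTRUE(connected) && psc_amplitude_pa != 0) {
    for (s in train$spike_times_ms) {
      onset <- stim_onset_ms + s + latency_ms
      cur <- cur - psc_amplitude_pa * psc_kernel(t_ms - onset, rise_ms, decay_ms)
    }
  }
  if (noise_sd_pa > 0) {
    if (!is.null(seed)) set.seed(seed)
    cur <- cur + stats::rnorm(length(cur), sd = noise_sd_pa)
  }
  structure(
    data.frame(time_ms = t_ms, current_pa = cur),
    class = c("screen_sweep", "data.frame"),
    stim_onset_ms = stim_onset_ms, sample_rate_hz = sample_rate_hz
  )
}

#' Average screening sweeps pointwise
#'
#' @param sweeps A list of `screen_sweep` objects on identical time grids
#'   (three repeats by convention).
#' @return A `screen_sweep` holding the pointwise mean current.
#' @export
average_sweeps <- function(sweeps) {
  if (length(sweeps) < 1L) stop_domain("need at least one sweep")
  grid <- sweeps[[1]]$time_ms
  for (s in sweeps[-1]) {
    if (length(s$time_ms) != length(grid) || any(s$time_ms != grid)) {
      stop_domain("sweeps are on mismatched time grids")
    }
  }
  avg <- rowMeans(do.call(cbind, lapply(sweeps, `[[`, "current_pa")))
  structure(
    data.frame(time_ms = grid, current_pa = avg),
    class = c("screen_sweep", "data.frame"),
    stim_onset_ms = attr(sweeps[[1]], "stim_onset_ms"),
    sample_rate_hz = attr(sweeps[[1]], "sample_rate_hz")
  )
}

#' Classify a connection from an averaged sweep
#'
#' For each presynaptic spike the evoked amplitude is measured as the
#' baseline-subtracted inward extremum (baseline mean minus trace minimum) in
#' the `(latency_window_ms[1], latency_window_ms[2])` window after the spike;
#' these per-spike amplitudes are reported. The detection statistic is the
#' amplitude of the stimulus-averaged response: the post-spike windows are
#' aligned and averaged across the spike train before taking the extremum,
#' the standard way evoked responses are pooled across a train. Averaging
#' across spikes suppresses the extremum bias of sampling noise (the minimum
#' of a noise-only window sits near 2.6 baseline SDs, while the averaged
#' response's noise floor is that divided by the square root of the number
#' of spikes), which is what makes a 3-SD threshold selective. Baseline mean
#' and SD come from the `baseline_ms` window immediately before stimulus
#' onset. The direction is classified connected when the mean evoked
#' amplitude exceeds `threshold_k` times the baseline noise SD.
#'
#' @param mean_sweep A `screen_sweep` (typically from [average_sweeps()]).
#' @param train The [build_stim_train()] used for the recording.
#' @param threshold_k Detection threshold in baseline SDs; default 3.
#' @param latency_window_ms Post-spike search window (ms); default c(2, 20).
#' @param baseline_ms Pre-stimulus baseline length (ms); default 50.
#' @param stim_onset_ms Stimulus onset within the sweep; defaults to the
#'   sweep's `stim_onset_ms` attribute.
#' @return A `screen_result`: list with `connected`,
#'   `mean_evoked_amplitude_pa`, `per_spike_amplitudes_pa`,
#'   `baseline_sd_pa`, `threshold_pa`.
#' @export
classify_connection <- function(mean_sweep, train, threshold_k = 3,
                                latency_window_ms = c(2, 20),
                                baseline_ms = 50,
                                stim_onset_ms = attr(mean_sweep, "stim_onset_ms")) {
  if (is.null(stim_onset_ms)) stop_domain("stimulus onset unknown")
  t_ms <- mean_sweep$time_ms
  cur <- mean_sweep$current_pa
  base_idx <- t_ms >= (stim_onset_ms - baseline_ms) & t_ms < stim_onset_ms
  if (!any(base_idx)) stop_domain("no samples in the baseline window")
  base_mean <- mean(cur[base_idx])
  base_sd <- stats::sd(cur[base_idx])
  if (is.na(base_sd)) base_sd <- 0
  windows <- lapply(train$spike_times_ms, function(s) {
    w <- which(t_ms >= (stim_onset_ms + s + latency_window_ms[1]) &
                 t_ms <= (stim_onset_ms + s + latency_window_ms[2]))
    if (!length(w)) stop_domain("evoked window extends past the end of the sweep")
    cur[w]
  })
  nw <- min(lengths(windows))
  amps <- vapply(windows, function(w) base_mean - min(w), numeric(1))
  # stimulus-averaged response: mean across aligned post-spike windows
  stacked <- vapply(windows, function(w) w[seq_len(nw)], numeric(nw))
  mean_amp <- base_mean - min(rowMeans(stacked))
  structure(
    list(
      connected = mean_amp > threshold_k * base_sd,
      mean_evoked_amplitude_pa = mean_amp,
      per_spike_amplitudes_pa = amps,
      baseline_sd_pa = base_sd,
      threshold_pa = threshold_k * base_sd
    ),
    class = "screen_result"
  )
}

#' Screen a held pair of cells in both directions
#'
#' Runs the stimulus/record protocol in each direction (cell A presynaptic
#' then cell B presynaptic), synthesizing `n_sweeps` sweeps per direction
#' from the supplied ground-truth connection flags, averaging, and
#' classifying. Each direction yields an independent result; a direction
#' whose cell fails quality control mid-screen is marked untested.
#'
#' @param cell_a,cell_b Cell ids.
#' @param connected_ab,connected_ba Ground-truth flags for the A->B and B->A
#'   directions.
#' @param train Stimulus train; default [build_stim_train()].
#' @param n_sweeps Sweeps per direction; default 3.
#' @param untested_ab,untested_ba Mark a direction untested (QC failure
#'   mid-screen); default FALSE.
#' @param seed Optional base seed; per-sweep seeds are derived from it.
#' @param ... Passed to [synthesize_sweep()] (amplitude, kinetics, noise).
#' @return A data frame with one row per direction: `pre`, `post`,
#'   `tested`, `connected`, `mean_evoked_amplitude_pa`.
#' @export
screen_pair <- function(cell_a, cell_b, connected_ab, connected_ba,
                        train = build_stim_train(), n_sweeps = 3L,
                        untested_ab = FALSE, untested_ba = FALSE,
                        seed = NULL, ...) {
  run_dir <- function(pre, post, truth, untested, offset) {
    if (untested) {
      return(data.frame(pre = pre, post = post, tested = FALSE,
                        connected = NA, mean_evoked_amplitude_pa = NA_real_))
    }
    sweeps <- lapply(seq_len(n_sweeps), function(i) {
      s <- if (is.null(seed)) NULL else seed + offset * 1000L + i
      synthesize_sweep(train, connected = truth, seed = s, ...)
    })
    res <- classify_connection(average_sweeps(sweeps), train)
    data.frame(pre = pre, post = post, tested = TRUE,
               connected = res$connected,
               mean_evoked_amplitude_pa = res$mean_evoked_amplitude_pa)
  }
  rbind(
    run_dir(cell_a, cell_b, connected_ab, untested_ab, 1L),
    run_dir(cell_b, cell_a, connected_ba, untested_ba, 2L)
  )
}
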