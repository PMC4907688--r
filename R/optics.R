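#' Voltage-sensor and camera parameters
#'
#' Describes the fluorescent voltage-indicator readout: a linear
#' fluorescence-voltage response with ~1 ms sensor lag, slow photobleach
#' decay under continuous red illumination, additive white readout noise and
#' boxcar frame integration at the camera frame rate.
#'
#' Default calibration: `sensitivity` is set so the reference cell's
#' light-evoked spike (rest -97.2 mV to peak ~+11 mV) reads out as a 3.5%
#' dF/F0 transient; `noise_sd` is set so that spike has a signal-to-noise
#' ratio of ~100 at the reference illumination and 100 Hz frame rate;
#' `bleach_rate` makes the baseline drop by 12% over 10 minutes.
#'
#' @param sensitivity Fractional dF/F0 per mV.
#' @param v_ref Reference voltage (mV) at which fluorescence equals the
#'   baseline F0; default is the dark resting potential.
#' @param tau_sensor Sensor response time constant (ms).
#' @param bleach_rate Photobleach rate (fraction of ln-intensity per
#'   minute); the default equals `-log(0.88)/10`.
#' @param noise_sd Additive Gaussian noise SD per frame, in fractional
#'   units of F0 at the reference illumination.
#' @param frame_rate Camera frame rate (Hz).
#' @param f0 Baseline intensity (arbitrary units).
#' @param shot_noise If `TRUE`, noise scales as `1/sqrt(rel_illumination)`
#'   (see `rel_illumination` in [voltage_to_fluorescence()]).
#'
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(sensitivity = 3.469420e-4,
                          v_ref = -97.2, tau_sensor = 1,
                          bleach_rate = -log(0.88) / 10,
                          noise_sd = 3.3e-4, frame_rate = 100,
                          f0 = 1000, shot_noise = FALSE) {
  if (sensitivity <= 0) stop("sensitivity must be positive")
  if (tau_sensor <= 0) stop("tau_sensor must be positive")
  b10 <- 1 - exp(-bleach_rate * 10)
  if (bleach_rate < 0 || b10 >= 1) stop("bleach over 10 min must lie in [0, 1)")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (f0 <= 0) stop("f0 must be positive")
  structure(list(sensitivity = sensitivity, v_ref = v_ref,
                 tau_sensor = tau_sensor, bleach_rate = bleach_rate,
                 noise_sd = noise_sd, frame_rate = frame_rate, f0 = f0,
                 shot_noise = shot_noise),
            class = "sensor_params")
}

#' Construct a fluorescence trace object
#'
#' @param well_id Well label.
#' @param times Sample times (s), uniform grid.
#' @param F Intensity per sample (positive).
#' @param stim_times Blue-pulse onset times (s).
#' @param frame_rate Frame rate (Hz).
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(well_id, times, F, stim_times = numeric(),
                               frame_rate = NULL) {
  if (length(times) != length(F)) stop("times and F must have equal length")
  if (any(F <= 0)) stop("fluorescence intensities must be positive")
  if (length(times) > 1) {
    dtv <- diff(times)
    if (max(abs(dtv - dtv[1])) > 1e-9) stop("times must be a uniform grid")
    if (is.null(frame_rate)) frame_rate <- 1 / dtv[1]
  }
  structure(list(well_id = well_id, times = times, F = F,
                 stim_times = stim_times, frame_rate = frame_rate),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace '%s': %d frames at %g Hz, %d stimuli\n",
              x$well_id, length(x$F), x$frame_rate, length(x$stim_times)))
  invisible(x)
}

#' @export
plot.fluorescence_trace <- function(x, ...) {
  graphics::plot(x$times, x$F, type = "l", xlab = "time (s)",
                 ylab = "intensity", ...)
  if (length(x$stim_times))
    graphics::abline(v = x$stim_times, col = "skyblue", lty = 3)
  invisible(x)
}

#' Render a simulated voltage trace as indicator fluorescence
#'
#' Applies, in order: a first-order low-pass filter with the sensor time
#' constant; the linear fluorescence-voltage map
#' `F = F0 * bleach(t) * (1 + sensitivity * (V - v_ref))`; boxcar averaging
#' of the fine-grid signal within each camera frame; and additive white
#' Gaussian readout noise per frame.  With `shot_noise = TRUE` in the
#' sensor the noise SD scales as `1/sqrt(rel_illumination)`.
#'
#' @param trace A `voltage_trace` from [simulate_free()].
#' @param sensor A [sensor_params()] object.
#' @param seed Integer seed for the noise generator (`NULL` leaves the RNG
#'   state untouched and draws from it).
#' @param well_id Label for the resulting trace.
#' @param t0_s Time already spent under imaging illumination at trace start
#'   (s); sets the initial photobleach state.
#' @param rel_illumination Red illumination relative to reference (used by
#'   the shot-noise option).
#'
#' @return A [fluorescence_trace()] sampled at the sensor frame rate.
#' @examples
#' vt <- simulate_free(pulse_train(2, 20, 50, 5), duration = 600)
#' ft <- voltage_to_fluorescence(vt, sensor_params(), seed = 1)
#' range(ft$F)
#' @export
voltage_to_fluorescence <- function(trace, sensor = sensor_params(),
                                    seed = NULL, well_id = "well",
                                    t0_s = 0, rel_illumination = 1) {
  d <- trace$data
  dt_ms <- d$t[2] - d$t[1]
  frame_ms <- 1000 / sensor$frame_rate
  per <- round(frame_ms / dt_ms)
  if (abs(per - frame_ms / dt_ms) > 1e-8)
    stop("voltage trace sampling must subdivide the camera frame evenly")
  n_frames <- floor((nrow(d) - 1) / per)
  if (n_frames < 1) stop("voltage trace shorter than one camera frame")

  # sensor low-pass (exact first-order recursive filter on the fine grid)
  a <- exp(-dt_ms / sensor$tau_sensor)
  v_lp <- as.numeric(stats::filter((1 - a) * d$V, a, method = "recursive",
                                   init = d$V[1]))
  # frame boxcar average
  idx <- seq_len(n_frames * per)
  v_frame <- colMeans(matrix(v_lp[idx], nrow = per))
  t_frame <- (seq_len(n_frames) - 0.5) * frame_ms / 1000   # s, frame centres

  bleach <- exp(-sensor$bleach_rate * (t0_s + t_frame) / 60)
  f_clean <- sensor$f0 * bleach *
    (1 + sensor$sensitivity * (v_frame - sensor$v_ref))
  sd_eff <- sensor$noise_sd *
    (if (sensor$shot_noise) 1 / sqrt(rel_illumination) else 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  noise <- if (sd_eff > 0) rnorm(n_frames, 0, sensor$f0 * sd_eff) else 0
  f_out <- f_clean + noise

  onsets <- if (!is.null(trace$stim_onsets)) trace$stim_onsets / 1000
            else numeric()
  fluorescence_trace(well_id, t_frame, f_out, stim_times = onsets,
                     frame_rate = sensor$frame_rate)
}

#' Signal-to-noise ratio of a fluorescence trace
#'
#' Mean spike height divided by the standard deviation of the detrended
#' baseline (all frames outside the spike search windows, detrended by
#' subtracting a running median so slow drift does not inflate the noise
#' estimate).
#'
#' @param trace A [fluorescence_trace()] (raw or photobleach-corrected).
#' @param spikes A [spike_train()] for the trace (see [extract_spikes()]).
#' @param search_ms Spike window length used to exclude spike frames (ms).
#' @param detrend_s Running-median window for baseline detrending (s).
#' @return SNR (dimensionless).  A noiseless trace (zero baseline SD)
#'   returns `Inf` with a warning.
#' @export
compute_snr <- function(trace, spikes, search_ms = 80, detrend_s = 1) {
  if (length(spikes$S) < 1) stop("at least one spike is required")
  in_spike <- rep(FALSE, length(trace$times))
  for (on in spikes$stim_times)
    in_spike <- in_spike | (trace$times >= on &
                              trace$times <= on + search_ms / 1000)
  base <- trace$F[!in_spike]
  if (length(base) < 20) stop("fewer than 20 baseline samples")
  k <- .odd_window(detrend_s * trace$frame_rate, length(base))
  resid <- base - .runmed_reflect(base, k)
  noise <- stats::sd(resid)
  height <- mean(spikes$S) * mean(base)  # S is in dF/F0 units
  if (noise == 0) {
    warning("zero baseline noise: SNR is infinite")
    return(Inf)
  }
  height / noise
}
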