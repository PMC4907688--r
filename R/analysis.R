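## Trace analysis: photobleach correction, background subtraction, spike
## extraction, use-dependence metrics, recovery curves and optical
## activation/inactivation curves.

.odd_window <- function(k, n) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (n %% 2L == 0L) n - 1L else n)
}

# running median with reflective edge padding
.runmed_reflect <- function(x, k) {
  n <- length(x)
  m <- (k - 1L) %/% 2L
  xp <- c(rev(x[seq_len(m) + 1L]), x, rev(x[(n - m):(n - 1L)]))
  stats::runmed(xp, k)[(m + 1L):(m + n)]
}

#' Photobleach correction by running-median division
#'
#' Divides the raw intensity by a running-median-filtered copy of itself,
#' yielding a dimensionless trace with baseline ~1.  The filter window must
#' be much longer than a spike (so spikes are not flattened) and much
#' shorter than the bleach time scale (so the slow decay is removed);
#' edges are handled by reflective padding.
#'
#' @param trace A [fluorescence_trace()].
#' @param window_s Median filter window (s); default 1 s against ~35 ms
#'   spikes and a ~50 min bleach constant.
#' @return A [fluorescence_trace()] with dimensionless intensities
#'   (attribute `corrected` set).
#' @examples
#' ft <- fluorescence_trace("w", seq(0, 5, 0.01), rep(100, 501))
#' range(photobleach_correct(ft)$F)   # exactly 1
#' @export
photobleach_correct <- function(trace, window_s = 1) {
  n <- length(trace$F)
  k <- .odd_window(window_s * trace$frame_rate, n)
  if (window_s * trace$frame_rate >= n)
    stop("median window must be shorter than the trace")
  out <- trace
  out$F <- trace$F / .runmed_reflect(trace$F, k)
  attr(out, "corrected") <- TRUE
  out
}

#' Subtract background fluorescence
#'
#' Removes the camera/autofluorescence background (measured from wells with
#' indicator-free cells) before dF/F0 computation.
#'
#' @param trace A [fluorescence_trace()].
#' @param background_level Background intensity; must be below every sample.
#' @return The background-subtracted [fluorescence_trace()].
#' @export
subtract_background <- function(trace, background_level) {
  if (any(trace$F <= background_level))
    stop("background level must be below all trace values")
  trace$F <- trace$F - background_level
  trace
}

#' Per-stimulus spike train
#'
#' Container for per-stimulus spike amplitudes `S` (dF/F0 units) and their
#' normalised form `S_norm = S / S[1]`.
#'
#' @param S Spike amplitudes per stimulus.
#' @param stim_times Stimulus onset times (s).
#' @param flagged Logical: `TRUE` when the reference spike failed the
#'   detection floor (well excluded from downstream statistics).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(S, stim_times = seq_along(S), flagged = FALSE) {
  S <- as.numeric(S)
  structure(list(S = S,
                 S_norm = if (!flagged && S[1] > 0) S / S[1]
                          else rep(NA_real_, length(S)),
                 stim_times = stim_times, flagged = flagged),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d stimuli%s\n  S: %s\n", length(x$S),
              if (x$flagged) " [flagged: no reference spike]" else "",
              paste(signif(x$S, 3), collapse = " ")))
  invisible(x)
}

#' Extract per-stimulus spike amplitudes
#'
#' For each stimulus onset, the spike amplitude is the maximum of the trace
#' within `search_ms` after the onset minus the mean of the baseline window
#' `baseline_ms` before it (the maximum point of the action potential minus
#' the baseline).  Ties at the maximum resolve to the earliest sample.
#' Wells whose first (reference) amplitude does not exceed `floor` are
#' flagged and excluded from normalised statistics, mirroring the exclusion
#' of anomalously spiking wells.
#'
#' @param trace A photobleach-corrected [fluorescence_trace()] (dimensionless,
#'   baseline ~1).
#' @param stim_times Stimulus onsets (s); defaults to those in the trace.
#' @param search_ms Search window after onset (ms).
#' @param baseline_ms Baseline window before onset (ms).
#' @param floor Detection floor for the reference spike (dF/F0 units).
#' @return A [spike_train()].
#' @export
extract_spikes <- function(trace, stim_times = trace$stim_times,
                           search_ms = 80, baseline_ms = 30,
                           floor = 0.005) {
  if (length(stim_times) < 1) stop("no stimulus onsets supplied")
  if (any(stim_times < min(trace$times) - 1e-9 |
            stim_times > max(trace$times) + 1e-9))
    stop("stimulus onsets outside the trace")
  S <- vapply(stim_times, function(on) {
    w <- trace$F[trace$times >= on - 1e-9 &
                   trace$times <= on + search_ms / 1000 + 1e-9]
    b <- trace$F[trace$times >= on - baseline_ms / 1000 - 1e-9 &
                   trace$times < on - 1e-9]
    if (length(b) == 0) b <- trace$F[1]
    max(w) - mean(b)
  }, numeric(1))
  spike_train(S, stim_times, flagged = S[1] <= floor)
}

#' Use-dependence index
#'
#' `Gamma = 1 - mean(S_norm[2..n])`: the fractional reduction of the spike
#' amplitude averaged over stimuli 2..n relative to the first stimulus.
#' Zero for a well with constant amplitudes; 1 for complete block after the
#' first spike.
#'
#' @param train A [spike_train()].
#' @return Gamma (dimensionless, <= 1).
#' @examples
#' use_dependence_index(spike_train(c(1, rep(0.5, 7))))   # 0.5
#' @export
use_dependence_index <- function(train) {
  n <- length(train$S)
  if (n < 2) stop("at least two stimuli are required")
  if (train$flagged) return(NA_real_)
  1 - mean(train$S_norm[2:n])
}

#' Spike-amplitude standard deviation
#'
#' Population (divide-by-n) standard deviation of the normalised spike
#' amplitudes, including the reference amplitude `S_norm[1] = 1` by
#' default.  Elevated both by monotone use-dependent block and by
#' alternating/erratic spike patterns.
#'
#' @param train A [spike_train()].
#' @param include_first Include `S_norm[1]` (default TRUE).
#' @param sample Use the sample (n-1) normalisation instead of the
#'   population (n) normalisation.
#' @return sigma (dimensionless, >= 0).
#' @export
amplitude_sd <- function(train, include_first = TRUE, sample = FALSE) {
  if (length(train$S) < 2) stop("at least two stimuli are required")
  if (train$flagged) return(NA_real_)
  x <- if (include_first) train$S_norm else train$S_norm[-1]
  if (sample) stats::sd(x)
  else sqrt(mean((x - mean(x))^2))
}

#' Recovery-from-inactivation curve and half-recovery time
#'
#' Given a family of test responses over increasing recovery intervals,
#' forms the ratio of each test amplitude to the amplitude at the longest
#' recovery time and interpolates the 50% crossing linearly in log(time)
#' (matching the geometric spacing of recovery intervals).  If the ratios
#' never bracket 0.5 the result is flagged `"<= min"` or `"> max"`.
#' Non-monotone families (beyond `tol`) are isotonised with a warning
#' before interpolation.
#'
#' @param trains A list of [spike_train()] objects (one per recovery time;
#'   the test-pulse amplitude is the last spike of each train), or a
#'   numeric vector of amplitudes/ratios.
#' @param recovery_ms Recovery intervals (ms), increasing, length >= 3.
#' @param normalize_to `"longest"` (default) divides by the value at the
#'   longest recovery; `"none"` uses the values as given.
#' @param tol Tolerated non-monotonicity before isotonisation.
#' @return A list with `table` (data.frame `recovery_ms`, `ratio`),
#'   `half_recovery_ms` (NA when flagged) and `flag`
#'   (`"ok"`, `"<= min"`, `"> max"`).
#' @export
recovery_curve <- function(trains, recovery_ms,
                           normalize_to = c("longest", "none"),
                           tol = 0.05) {
  normalize_to <- match.arg(normalize_to)
  if (length(recovery_ms) < 3 || is.unsorted(recovery_ms, strictly = TRUE))
    stop("need >= 3 strictly increasing recovery times")
  amp <- if (is.numeric(trains)) trains
         else vapply(trains, function(tr) tr$S[length(tr$S)], numeric(1))
  if (length(amp) != length(recovery_ms))
    stop("one amplitude per recovery time is required")
  ratio <- if (normalize_to == "longest") amp / amp[length(amp)] else amp
  r_fit <- ratio
  if (any(diff(ratio) < -tol)) {
    warning("non-monotone recovery ratios: interpolating on isotonic fit")
    r_fit <- stats::isoreg(log(recovery_ms), ratio)$yf
  }
  flag <- "ok"; half <- NA_real_
  if (r_fit[1] >= 0.5) flag <- "<= min"
  else if (all(r_fit < 0.5)) flag <- "> max"
  else {
    i <- which(r_fit >= 0.5)[1]          # first crossing from below
    lt <- log(recovery_ms)
    half <- exp(lt[i - 1] + (0.5 - r_fit[i - 1]) /
                  (r_fit[i] - r_fit[i - 1]) * (lt[i] - lt[i - 1]))
  }
  list(table = data.frame(recovery_ms = recovery_ms, ratio = ratio),
       half_recovery_ms = half, flag = flag)
}

#' Optical activation and inactivation curves
#'
#' From an intensity-staircase family (see [intensity_staircase()]), the
#' prepulse-onset response amplitude is the activation proxy and the
#' test-pulse amplitude the inactivation (availability) proxy; both are
#' normalised to the maximum amplitude observed across the family, as in
#' the normalisation of spike amplitudes to the per-trace maximum.
#'
#' @param trains A list of [spike_train()] objects, one per staircase
#'   intensity, each holding the prepulse-onset and test-pulse amplitudes
#'   (in that order).
#' @param intensities Prepulse intensities (mW/cm^2).
#' @return A data.frame with columns `intensity`, `activation`,
#'   `inactivation`.
#' @export
activation_inactivation <- function(trains, intensities) {
  if (length(trains) != length(intensities))
    stop("one spike train per staircase intensity is required")
  act <- vapply(trains, function(tr) max(tr$S[1], 0), numeric(1))
  inact <- vapply(trains, function(tr) max(tr$S[2], 0), numeric(1))
  mx <- max(act, inact)
  if (mx <= 0) stop("no responses detected in the staircase family")
  data.frame(intensity = intensities,
             activation = act / mx, inactivation = inact / mx)
}
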