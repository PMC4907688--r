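#' Piecewise-constant blue-light stimulus protocol
#'
#' A light protocol is an ordered list of `(duration_ms, intensity)`
#' segments plus the derived onset times of its light pulses (needed by the
#' analysis layer to window spikes).  All stimuli used by the platform are
#' square pulses; total protocol duration is capped at 35 s, the longest
#' per-well measurement the assay design allows.
#'
#' @param duration_ms Segment durations (ms), positive.
#' @param intensity Segment light intensities (mW/cm^2), non-negative.
#' @param label Protocol label.
#' @return An object of class `light_protocol` with fields `segments`
#'   (data.frame `duration_ms`, `intensity`), `stim_onsets` (ms) and `label`.
#' @seealso [pulse_train()], [prepulse_recovery_test()], [intensity_staircase()]
#' @export
light_protocol <- function(duration_ms, intensity, label = "protocol") {
  if (length(duration_ms) != length(intensity))
    stop("duration_ms and intensity must have equal length")
  if (length(duration_ms) == 0) stop("protocol needs at least one segment")
  if (any(duration_ms <= 0)) stop("segment durations must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (sum(duration_ms) > 35000)
    stop("total protocol duration exceeds 35 s")
  seg <- data.frame(duration_ms = as.numeric(duration_ms),
                    intensity = as.numeric(intensity))
  starts <- cumsum(c(0, seg$duration_ms))[seq_len(nrow(seg))]
  dark_before <- c(TRUE, seg$intensity[-nrow(seg)] == 0)
  onsets <- starts[seg$intensity > 0 & dark_before]
  structure(list(segments = seg, stim_onsets = onsets, label = label),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat(sprintf("Light protocol '%s': %d segments, %g ms total, %d pulse onsets\n",
              x$label, nrow(x$segments), protocol_span(x),
              length(x$stim_onsets)))
  invisible(x)
}

#' Total span of a protocol in ms
#' @param protocol A [light_protocol()].
#' @return Span in ms.
#' @export
protocol_span <- function(protocol) sum(protocol$segments$duration_ms)

#' Regular pulse train
#'
#' `n_pulses` square pulses of `pulse_ms` at `intensity`, delivered at
#' `rate_hz`; pulse onsets fall at `k / rate_hz`.  The canonical screen
#' stimulus is eight 20-ms pulses of 50 mW/cm^2 at 10 Hz.
#'
#' @param n_pulses Number of pulses (>= 1).
#' @param pulse_ms Pulse duration (ms); must be shorter than the period.
#' @param intensity Light intensity (mW/cm^2).
#' @param rate_hz Repetition rate (Hz).
#' @return A [light_protocol()].
#' @examples
#' pulse_train(8, 20, 50, 10)   # 720 ms span, onsets 100 ms apart
#' @export
pulse_train <- function(n_pulses, pulse_ms, intensity, rate_hz) {
  stopifnot(n_pulses >= 1, pulse_ms > 0, rate_hz > 0)
  period <- 1000 / rate_hz
  if (n_pulses > 1 && pulse_ms >= period)
    stop("pulses overlap: pulse_ms must be < 1000/rate_hz")
  dur <- c(rbind(rep(pulse_ms, n_pulses),
                 rep(period - pulse_ms, n_pulses)))
  int <- c(rbind(rep(intensity, n_pulses), rep(0, n_pulses)))
  dur <- dur[-length(dur)]       # drop trailing dark gap
  int <- int[-length(int)]
  if (n_pulses == 1) { dur <- pulse_ms; int <- intensity }
  light_protocol(dur, int,
                 label = sprintf("%dx%gms@%gHz", n_pulses, pulse_ms, rate_hz))
}

#' Prepulse / recovery / test protocol
#'
#' A depolarising light prepulse (which populates the inactivated state and
#' allows drug binding), a dark recovery interval, and a brief test pulse
#' probing residual excitability.
#'
#' @param prepulse_ms,prepulse_mw Duration and intensity of the prepulse.
#' @param recovery_ms Dark recovery interval (ms); 0 gives two contiguous
#'   pulses.
#' @param test_ms,test_mw Duration and intensity of the test pulse.
#' @param tail_ms Dark tail appended after the test pulse (ms).
#' @return A [light_protocol()] with two stimulus onsets (one when
#'   `recovery_ms = 0`).
#' @examples
#' prepulse_recovery_test(500, 50, 200, 30, 50)
#' @export
prepulse_recovery_test <- function(prepulse_ms, prepulse_mw, recovery_ms,
                                   test_ms, test_mw, tail_ms = 200) {
  stopifnot(prepulse_ms > 0, test_ms > 0, recovery_ms >= 0, tail_ms >= 0)
  dur <- c(prepulse_ms, recovery_ms, test_ms, tail_ms)
  int <- c(prepulse_mw, 0, test_mw, 0)
  keep <- dur > 0
  light_protocol(dur[keep], int[keep],
                 label = sprintf("prepulse%g/rec%g/test%g",
                                 prepulse_ms, recovery_ms, test_ms))
}

#' Intensity-staircase family for optical activation/inactivation curves
#'
#' One protocol per prepulse intensity: a long conditioning prepulse of
#' graded intensity immediately followed by a fixed bright test pulse.
#' The prepulse-onset spike probes activation; the test-pulse spike probes
#' availability (inactivation) after the conditioning depolarisation.
#'
#' @param prepulse_ms Prepulse duration (ms); the assay default is 1000 ms.
#' @param intensities Non-decreasing prepulse intensities (mW/cm^2); the
#'   assay default staircase is 1.7, 3.6, 6.3, 9.8, 14.
#' @param test_ms,test_mw Test-pulse duration and intensity (150 ms,
#'   14 mW/cm^2 by default).
#' @param tail_ms Dark tail after the test pulse (ms).
#' @return A list of [light_protocol()] objects, one per intensity, with
#'   attribute `intensities`.
#' @export
intensity_staircase <- function(prepulse_ms = 1000,
                                intensities = c(1.7, 3.6, 6.3, 9.8, 14),
                                test_ms = 150, test_mw = 14, tail_ms = 300) {
  if (length(intensities) == 0) stop("intensities must be non-empty")
  if (is.unsorted(intensities)) stop("intensities must be non-decreasing")
  fam <- lapply(intensities, function(iw) {
    dur <- c(prepulse_ms, test_ms, tail_ms)
    int <- c(iw, test_mw, 0)
    pr <- light_protocol(dur, int,
                         label = sprintf("staircase@%g", iw))
    # the test pulse is contiguous with the prepulse: tag both onsets
    pr$stim_onsets <- c(0, prepulse_ms)
    pr
  })
  attr(fam, "intensities") <- as.numeric(intensities)
  fam
}

#' Read / write protocol files
#'
#' Delimited-text serialisation (tab-separated: `segment`, `duration_ms`,
#' `intensity`); round-trips are lossless.
#'
#' @param protocol A [light_protocol()].
#' @param path File path.
#' @return `read_protocol` returns a [light_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  df <- cbind(segment = seq_len(nrow(protocol$segments)), protocol$segments)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @param label Label for the protocol read back.
#' @export
read_protocol <- function(path, label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  light_protocol(df$duration_ms, df$intensity, label = label)
}
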