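## Screen statistics: Z-prime, hit calling, alternation score.

#' Z-prime assay-quality factor
#'
#' `Z' = 1 - 3 * (sd_p + sd_n) / |mean_p - mean_n|` with sample (n-1)
#' standard deviations, the screening-literature convention.  Equals 1 for
#' zero-variance groups and degrades as the control distributions overlap;
#' values >= 0.5 indicate a robust high-throughput assay.
#'
#' @param pos_values Positive-control values (>= 2).
#' @param neg_values Negative-control values (>= 2).
#' @return Z-prime (dimensionless, <= 1).
#' @examples
#' zprime(c(1, 1, 1), c(0, 0, 0))   # 1
#' @export
zprime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop("each control group needs >= 2 values")
  mp <- mean(pos_values); mn <- mean(neg_values)
  if (mp == mn) stop("Z-prime undefined: control means are equal")
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / abs(mp - mn)
}

#' Call hits by the 5-SD sigma rule
#'
#' A test well is a hit when its spike-amplitude SD exceeds the
#' negative-control mean by more than five negative-control (sample)
#' standard deviations.  Control wells are never flagged.
#'
#' @param sigma Per-well sigma values.
#' @param role Per-well role: `"negative_control"`, `"positive_control"`,
#'   `"test"` or `"empty"`.
#' @param n_sd Threshold multiplier (default 5).
#' @return Logical hit flags (same length; `NA` sigma never flags).
#' @export
call_hits <- function(sigma, role, n_sd = 5) {
  neg <- sigma[role == "negative_control" & !is.na(sigma)]
  if (length(neg) < 4) stop("need >= 4 negative-control wells")
  thr <- mean(neg) + n_sd * stats::sd(neg)
  hit <- role == "test" & !is.na(sigma) & sigma > thr
  attr(hit, "threshold") <- thr
  hit
}

#' Alternation score of a spike train
#'
#' Mean absolute lag-1 difference of the normalised amplitudes minus the
#' mean absolute lag-2 difference.  Positive values indicate an
#' even/odd alternating (alternans) pattern; monotone decay gives values
#' <= 0 and a constant train gives 0.
#'
#' @param train A [spike_train()] (>= 4 stimuli).
#' @return Alternation score (dimensionless).
#' @examples
#' alternation_score(spike_train(c(1, 0, 1, 0, 1, 0, 1, 0)))   # 1
#' @export
alternation_score <- function(train) {
  if (length(train$S) < 4) stop("at least four stimuli are required")
  if (train$flagged) return(NA_real_)
  s <- train$S_norm
  n <- length(s)
  mean(abs(s[-1] - s[-n])) - mean(abs(s[-(1:2)] - s[1:(n - 2)]))
}
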