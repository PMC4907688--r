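make_trace <- function(f, frame_rate = 100, onsets = numeric()) {
  fluorescence_trace("w", (seq_along(f) - 1) / frame_rate, f,
                     stim_times = onsets)
}

test_that("photobleach correction flattens trends and preserves spikes", {
  # constant trace -> exactly 1
  ct <- photobleach_correct(make_trace(rep(250, 600)))
  expect_true(all(ct$F == 1))
  # slow exponential decay (12% per 10 min) with no spikes -> within 0.5%
  t <- (0:5999) / 100
  decay <- 1000 * exp(log(0.88) * t / 600)
  cd <- photobleach_correct(make_trace(decay))
  expect_true(all(cd$F > 0.995 & cd$F < 1.005))
  # planted 3.5% spikes on the decaying baseline recover within 5%
  onsets <- c(10, 20, 30, 40)
  f <- decay
  for (on in onsets) {
    idx <- which(t >= on & t < on + 0.03)
    f[idx] <- f[idx] * 1.035
  }
  st <- extract_spikes(photobleach_correct(make_trace(f, onsets = onsets)))
  expect_true(all(abs(st$S - 0.035) / 0.035 < 0.05))
  expect_error(photobleach_correct(make_trace(rep(1, 50)), window_s = 1),
               "shorter")
})

test_that("background subtraction validates and shifts", {
  tr <- make_trace(rep(110, 300))
  expect_equal(subtract_background(tr, 0)$F, tr$F)
  expect_equal(subtract_background(tr, 10)$F, rep(100, 300))
  expect_error(subtract_background(tr, 110), "below")
})

test_that("spike extraction recovers planted amplitudes exactly", {
  t <- (0:999) / 100
  onsets <- c(2, 4, 6)
  amps <- c(0.035, 0.020, 0.010)
  f <- rep(1, 1000)
  for (i in seq_along(onsets))
    f[t >= onsets[i] & t < onsets[i] + 0.03] <- 1 + amps[i]
  st <- extract_spikes(make_trace(f, onsets = onsets))
  expect_equal(st$S, amps)
  expect_equal(st$S_norm, amps / amps[1])
  expect_false(st$flagged)
  # flat trace: all amplitudes ~0 and the well is flagged
  flat <- extract_spikes(make_trace(rep(1, 1000), onsets = onsets))
  expect_true(flat$flagged)
  expect_true(all(abs(flat$S) < 1e-12))
  expect_true(all(is.na(flat$S_norm)))
})

test_that("gamma and sigma match their formulas and brute force", {
  expect_equal(use_dependence_index(spike_train(rep(1, 8))), 0)
  expect_equal(use_dependence_index(spike_train(c(1, rep(0.5, 7)))), 0.5)
  expect_equal(use_dependence_index(spike_train(c(1, rep(0, 7)))), 1)
  expect_equal(amplitude_sd(spike_train(rep(2, 8))), 0)
  expect_equal(amplitude_sd(spike_train(c(1, 0, 1, 0, 1, 0, 1, 0))), 0.5)
  expect_error(use_dependence_index(spike_train(1)), "two")
  set.seed(42)
  for (i in 1:25) {
    S <- runif(8, 0.2, 2)
    st <- spike_train(S)
    sn <- S / S[1]
    expect_equal(use_dependence_index(st), 1 - sum(sn[2:8]) / 7,
                 tolerance = 1e-12)
    expect_equal(amplitude_sd(st),
                 sqrt(sum((sn - sum(sn) / 8)^2) / 8), tolerance = 1e-12)
    # invariance under uniform rescaling of the raw amplitudes
    sc <- runif(1, 0.1, 10)
    expect_equal(use_dependence_index(spike_train(S * sc)),
                 use_dependence_index(st), tolerance = 1e-12)
    expect_equal(amplitude_sd(spike_train(S * sc)), amplitude_sd(st),
                 tolerance = 1e-12)
  }
  # sample-normalisation and first-spike options
  st <- spike_train(c(1, 0.8, 0.6, 0.4))
  expect_equal(amplitude_sd(st, sample = TRUE), sd(st$S_norm))
  expect_equal(amplitude_sd(st, include_first = FALSE),
               sqrt(mean((st$S_norm[-1] - mean(st$S_norm[-1]))^2)))
})

test_that("noisy planted amplitudes are recovered within 5% on average", {
  t <- (0:599) / 100
  onsets <- seq(0.5, 5, 0.5)
  decay <- exp(log(0.88) * t / 600)
  clean <- decay
  for (on in onsets) {
    idx <- which(t >= on & t < on + 0.03)
    clean[idx] <- clean[idx] * 1.035
  }
  set.seed(7)
  err <- replicate(100, {
    f <- clean + rnorm(length(t), 0, 3.5e-4)   # SNR ~ 100
    st <- extract_spikes(photobleach_correct(make_trace(f, onsets = onsets)))
    mean(abs(st$S - 0.035) / 0.035)
  })
  expect_lt(mean(err), 0.05)
})

test_that("recovery curves interpolate and flag correctly", {
  dts <- 40 * 2^(0:7)
  # exponential repriming with time constant tau: half-time = tau * ln 2
  tau <- 300
  ratios <- 1 - exp(-dts / tau)
  rc <- recovery_curve(ratios, dts, normalize_to = "none")
  expect_equal(rc$half_recovery_ms, tau * log(2), tolerance = 0.03)
  # full recovery at all delays: flagged at or below the shortest delay
  rc1 <- recovery_curve(rep(1, 8) + rnorm(8, 0, 1e-3), dts)
  expect_identical(rc1$flag, "<= min")
  expect_true(is.na(rc1$half_recovery_ms))
  # no recovery: beyond the longest delay
  rc2 <- recovery_curve(seq(0.05, 0.3, length.out = 8), dts,
                        normalize_to = "none")
  expect_identical(rc2$flag, "> max")
  # non-monotone families are isotonised with a warning
  wob <- 1 - exp(-dts / tau); wob[4] <- wob[3] - 0.1
  expect_warning(recovery_curve(wob, dts, normalize_to = "none"),
                 "isotonic")
  expect_error(recovery_curve(c(1, 1), c(10, 20)), ">= 3")
})

test_that("staircase activation rises and inactivation falls; shifters move only inactivation", {
  run_family <- function(drug = NULL) {
    fam <- intensity_staircase()
    trains <- lapply(fam, function(pr) {
      vt <- simulate_free(pr, drug = drug)$data
      amps <- vapply(pr$stim_onsets, function(on) {
        base <- if (on == 0) vt$V[1]
                else mean(vt$V[vt$t >= on - 30 & vt$t < on])
        max(vt$V[vt$t >= on & vt$t <= on + 150]) - base
      }, numeric(1))
      spike_train(amps, pr$stim_onsets)
    })
    activation_inactivation(trains, attr(fam, "intensities"))
  }
  ctrl <- run_family()
  expect_true(all(diff(ctrl$activation) > -1e-9))     # rises with intensity
  expect_true(all(diff(ctrl$inactivation) < 1e-9))    # falls with intensity
  expect_gt(max(ctrl$activation), max(ctrl$inactivation[5], 0.0))
  # curves cross inside the staircase range
  expect_true(any(ctrl$activation > ctrl$inactivation) &&
                any(ctrl$activation < ctrl$inactivation))
  shift <- run_family(drug_preset("carbamazepine"))
  # inactivation curve shifted left: availability consistently lower across
  # the interior of the staircase (the shift acts through the NaV window
  # current, so the displacement is systematic but modest)
  mid <- 1:4
  expect_true(all(shift$inactivation[mid] < ctrl$inactivation[mid] - 0.005))
  # activation proxy essentially unchanged (< 2%)
  expect_lt(max(abs(shift$activation - ctrl$activation)), 0.02)
})
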