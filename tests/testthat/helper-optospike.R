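# Shared fixtures for the simulation tests.

# screen-style stimulus with a dark lead-in, as used on plates
screen_protocol <- function(lead_ms = 500, n = 8, rate_hz = 10) {
  pr <- pulse_train(n, 20, 50, rate_hz)
  full <- light_protocol(c(lead_ms, pr$segments$duration_ms),
                         c(0, pr$segments$intensity))
  full$stim_onsets <- pr$stim_onsets + lead_ms
  full
}

# per-stimulus voltage-level spike amplitudes (max - pre-onset baseline)
train_amplitudes <- function(drug = NULL, n = 8, hz = 10,
                             cell = default_cell(), duration = NULL) {
  if (is.null(duration)) duration <- n * 1000 / hz + 200
  v <- simulate_free(pulse_train(n, 20, 50, hz), cell = cell, drug = drug,
                     duration = duration)$data
  onsets <- (seq_len(n) - 1) * 1000 / hz
  vapply(onsets, function(o) {
    base <- if (o == 0) v$V[1] else mean(v$V[v$t >= o - 30 & v$t < o])
    max(v$V[v$t >= o & v$t <= o + 80]) - base
  }, numeric(1))
}

# test/prepulse peak NaV current ratios for the repriming protocol
vc_recovery_ratios <- function(drug = NULL, recovery_ms = 2^(0:8),
                               cell = default_cell()) {
  vapply(recovery_ms, function(d) {
    cmd <- rbind(c(300, -100), c(200, 0), c(d, -100), c(100, 0))
    dd <- simulate_voltage_clamp(cmd, cell = cell, drug = drug,
                                 record_dt = 0.01)$data
    pre <- min(dd$J_nav[dd$t >= 300 & dd$t < 320])
    tst <- min(dd$J_nav[dd$t >= 500 + d & dd$t < 520 + d])
    tst / pre
  }, numeric(1))
}

# peak step-evoked NaV current over a grid of step potentials
nav_iv_peaks <- function(cell = default_cell(), steps = seq(-70, 20, 10)) {
  vapply(steps, function(v) {
    dd <- simulate_voltage_clamp(rbind(c(60, -100), c(15, v)), cell = cell,
                                 record_dt = 0.01)$data
    min(dd$J_nav)
  }, numeric(1))
}

# optical test-pulse amplitudes for the repriming family (voltage level)
optical_recovery_amps <- function(drug = NULL,
                                  recovery_ms = 40 * 2^(0:7),
                                  cell = default_cell()) {
  vapply(recovery_ms, function(d) {
    pr <- prepulse_recovery_test(500, 50, d, 20, 50, tail_ms = 150)
    vt <- simulate_free(pr, cell = cell, drug = drug)$data
    on <- 500 + d
    base <- mean(vt$V[vt$t >= on - 30 & vt$t < on])
    max(vt$V[vt$t >= on & vt$t <= on + 80]) - base
  }, numeric(1))
}
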