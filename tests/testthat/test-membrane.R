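cell <- default_cell()
cond <- ionic_conditions()
e_k <- nernst_potential(2, 140, 23, 1)

test_that("channelrhodopsin photocurrent: reversal, saturation, EPD50", {
  expect_equal(cheriff_current(4, 100), 0)
  expect_equal(cheriff_current(4, 0), 0)
  # saturating steady-state density at -60 mV is the calibration anchor
  expect_equal(cheriff_current(-60, 1e9), -13.0, tolerance = 1e-6)
  # at the EPD50 the steady-state current is half of saturating
  expect_equal(cheriff_current(-60, cell$chr_epd50),
               cheriff_current(-60, 1e9) / 2, tolerance = 1e-6)
  expect_error(cheriff_current(-60, -1), "non-negative")
})

test_that("inward-rectifier current rectifies around E_K", {
  expect_equal(kir_current(e_k, cond, cell), 0)
  expect_gt(abs(kir_current(e_k - 30, cond, cell)),
            abs(kir_current(e_k + 60, cond, cell)))
  # closed-form substitution oracle with explicit rectification parameters
  c2 <- cell_params(g_kir = 1, kir_rect_vhalf = -10, kir_rect_slope = 10)
  v <- e_k + 20
  by_hand <- 1 * (1 / (1 + exp((20 - (-10)) / 10))) * 20
  expect_equal(kir_current(v, cond, c2), by_hand, tolerance = 1e-12)
})

test_that("NaV current density obeys gating, block and full-block limits", {
  expect_equal(nav_current(-20, m = 0.9, h = 0.8, B = 1), 0)
  e_na <- nernst_potential(140, 10, 23, 1)
  expect_equal(nav_current(-20, 1, 1), cell$g_nav * (-20 - e_na))
  expect_error(nav_current(-20, m = 1.2, h = 0.5))
  # tonic drug at its resting Kd gives half occupancy
  ttx_like <- drug_model("t", "tonic", concentration = 2, kd_rest = 2)
  expect_equal(nav_current(-20, 1, 1, drug = ttx_like),
               nav_current(-20, 1, 1) / 2)
})

test_that("step-protocol IV peaks at -20 mV with -61.4 pA/pF", {
  steps <- seq(-70, 20, 10)
  pk <- nav_iv_peaks(cell, steps)
  expect_equal(steps[which.min(pk)], -20)
  expect_equal(min(pk), -61.4, tolerance = 1e-3)
  # tonic block at Kd: occupancy 1/2 up to the weak (2x) inactivated-state
  # affinity gain at the -100 mV holding potential
  half <- drug_model("t", "tonic", concentration = 5, kd_rest = 5,
                     tonic_tau = 1e9)
  dd <- simulate_voltage_clamp(rbind(c(60, -100), c(15, -20)), cell = cell,
                               drug = half, record_dt = 0.01)$data
  f_i <- 1 - nav_h_inf(-100, cell)
  b_hold <- 5 / (5 + 5 / (1 + f_i))
  expect_equal(min(dd$J_nav), -61.4 * (1 - b_hold), tolerance = 0.005)
  expect_equal(min(dd$J_nav), -61.4 / 2, tolerance = 0.03)
})

test_that("guarded-receptor block update matches its closed form", {
  dr <- drug_model("d", "state_dependent", concentration = 5,
                   k_on = 2, k_off = 3)
  # unbinding-only decay at zero concentration
  dr0 <- drug_model("d", "state_dependent", concentration = 0,
                    k_on = 2, k_off = 3)
  B1 <- drug_block_step(0.8, -97, dr0, dt = 100)
  expect_equal(B1, 0.8 * exp(-100 * 3 / 1000), tolerance = 1e-12)
  # absorbing limit: k_off = 0 under sustained depolarisation
  dr_abs <- drug_model("d", "state_dependent", concentration = 50,
                       k_on = 2, k_off = 0)
  B <- 0
  for (i in 1:200) B <- drug_block_step(B, 0, dr_abs, dt = 10)
  expect_gt(B, 0.999)
  # equilibrium fixed point matches alpha/(alpha+beta) at frozen voltage
  f_i <- 1 - nav_h_inf(-40, cell)
  b_star <- (2 * 5 * f_i) / (2 * 5 * f_i + 3)
  B <- 0.2
  for (i in 1:5000) B <- drug_block_step(B, -40, dr, dt = 1)
  expect_equal(B, b_star, tolerance = 1e-6)
})

test_that("free-running simulation reproduces rest and light-evoked spikes", {
  vt <- simulate_free(light_protocol(50, 0), duration = 50)
  expect_equal(vt$data$V[1], -97.2, tolerance = 0.01)
  expect_lt(diff(range(vt$data$V)), 0.01)   # dark steady state
  spike <- simulate_free(pulse_train(1, 20, 50, 5), duration = 250)
  expect_gt(max(spike$data$V), 0)           # overshooting spike
  # conservation: with all conductances off the voltage never moves
  dead <- cell_params(g_nav = 0, g_kir = 0, g_chr = 0, g_leak = 0)
  vt0 <- simulate_free(pulse_train(1, 20, 50, 5), cell = dead,
                       duration = 100, init_v = -50)
  expect_equal(range(vt0$data$V), c(-50, -50))
  expect_error(simulate_free(pulse_train(1, 20, 50, 5), dt = 0.05), "dt")
})

test_that("voltage clamp holds the command and reprimes in 4.5 ms", {
  hold <- simulate_voltage_clamp(cbind(100, -100))
  expect_true(all(hold$data$V == -100))
  expect_lt(max(abs(hold$data$J_nav)), 0.05)  # h ~ 1, m ~ 0: no current
  r <- vc_recovery_ratios()
  rc <- recovery_curve(r, 2^(0:8), normalize_to = "none")
  expect_equal(rc$half_recovery_ms, 4.5, tolerance = 0.05)
  expect_gt(r[9], 0.99)                       # complete recovery by 256 ms
})

test_that("fast- and slow-unbinding blockers reprime as calibrated", {
  fast <- drug_preset("alternans")            # k_off set for 20 ms repriming
  rf <- recovery_curve(vc_recovery_ratios(fast), 2^(0:8),
                       normalize_to = "none")
  expect_equal(rf$half_recovery_ms, 20, tolerance = 0.15)
  slow <- drug_preset("amitriptyline")        # 10 uM strong blocker
  rs <- vc_recovery_ratios(slow)
  expect_lt(rs[9], 0.5)                       # < 50% recovery at 256 ms
})
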