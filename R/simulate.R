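## Simulation front ends around the compiled fixed-step integrator.

.pack_params <- function(cell, drug, conditions) {
  ek <- nernst_potential(conditions$k_out, conditions$k_in,
                         conditions$temperature, 1)
  ena <- nernst_potential(conditions$na_out, conditions$na_in,
                          conditions$temperature, 1)
  scheme <- match(drug$scheme,
                  c("none", "tonic", "state_dependent", "gating_shift")) - 1L
  inact_vh <- cell$nav_inact_vhalf +
    if (drug$scheme == "gating_shift") drug$inact_shift else 0
  c(cell$g_nav, cell$nav_act_vhalf, cell$nav_act_slope,
    inact_vh, cell$nav_inact_slope,
    cell$nav_tau_m, cell$nav_tau_h,
    ena,
    cell$g_kir, ek, cell$kir_rect_vhalf, cell$kir_rect_slope,
    cell$g_chr, cell$e_chr, cell$chr_epd50, cell$chr_tau_on,
    cell$chr_tau_off, cell$chr_rect_vhalf, cell$chr_rect_slope,
    cell$g_kv43, cell$kv43_act_vhalf, cell$kv43_act_slope,
    cell$kv43_tau_act, cell$kv43_inact_vhalf, cell$kv43_inact_slope,
    cell$kv43_tau_fast, cell$kv43_tau_slow, cell$kv43_frac_fast,
    cell$kv43_tau_deact,
    cell$g_leak, cell$e_leak,
    scheme, drug$concentration, drug$k_on, drug$k_off,
    if (is.finite(drug$kd_rest)) drug$kd_rest else 1e30,
    drug$state_preference, drug$tonic_tau, 2)
}

.no_drug <- function() drug_model("none", scheme = "none")

# net steady-state current density at voltage v (dark, gates at steady state)
.steady_current <- function(v, cell, drug, conditions) {
  shift <- if (drug$scheme == "gating_shift") drug$inact_shift else 0
  m <- nav_m_inf(v, cell)
  h <- nav_h_inf(v, cell, shift)
  B <- .equilibrium_block(v, cell, drug, shift)
  ek <- nernst_potential(conditions$k_out, conditions$k_in,
                         conditions$temperature, 1)
  iinf <- boltz_down(v, cell$kv43_inact_vhalf, cell$kv43_inact_slope)
  ainf <- boltz_up(v, cell$kv43_act_vhalf, cell$kv43_act_slope)
  nav_current(v, m, h, B = B, conditions = conditions, cell = cell) +
    kir_current(v, conditions, cell) +
    cell$g_kv43 * ainf^4 * iinf * (v - ek) +
    cell$g_leak * (v - cell$e_leak)
}

.equilibrium_block <- function(v, cell, drug, shift = 0) {
  f_i <- 1 - nav_h_inf(v, cell, shift)
  switch(drug$scheme,
    none = 0,
    gating_shift = 0,
    tonic = {
      kd_eff <- drug$kd_rest / (1 + f_i)
      drug$concentration / (drug$concentration + kd_eff)
    },
    state_dependent = {
      f_bind <- drug$state_preference * f_i + (1 - drug$state_preference)
      a <- drug$k_on * drug$concentration * f_bind
      if (a + drug$k_off == 0) 0 else a / (a + drug$k_off)
    })
}

#' Dark resting potential of the model cell
#'
#' Solves the zero of the steady-state membrane current (all gates at their
#' voltage steady state, light off, drug block at equilibrium).  With the
#' calibrated default cell in a 2 mM K+ bath this is -97.2 mV, a few mV
#' depolarised from E_K, and it follows the Nernst line approximately as
#' bath K+ is varied.
#'
#' @param cell A [cell_params()] object.
#' @param drug A [drug_model()] (default: drug-free).
#' @param conditions An [ionic_conditions()] object.
#' @return Resting potential (mV).
#' @examples
#' resting_potential()                                  # -97.2 mV
#' resting_potential(conditions = ionic_conditions(k_out = 8))
#' @export
resting_potential <- function(cell = default_cell(), drug = NULL,
                              conditions = ionic_conditions()) {
  if (is.null(drug)) drug <- .no_drug()
  ek <- nernst_potential(conditions$k_out, conditions$k_in,
                         conditions$temperature, 1)
  stats::uniroot(function(v) .steady_current(v, cell, drug, conditions),
                 lower = ek - 1e-3, upper = 20, tol = 1e-10)$root
}

.init_state <- function(v0, light0, cell, drug, conditions) {
  shift <- if (drug$scheme == "gating_shift") drug$inact_shift else 0
  c(V = v0,
    m = nav_m_inf(v0, cell),
    h = nav_h_inf(v0, cell, shift),
    p = light0 / (light0 + cell$chr_epd50),
    a = boltz_up(v0, cell$kv43_act_vhalf, cell$kv43_act_slope),
    i_f = boltz_down(v0, cell$kv43_inact_vhalf, cell$kv43_inact_slope),
    i_s = boltz_down(v0, cell$kv43_inact_vhalf, cell$kv43_inact_slope),
    B = .equilibrium_block(v0, cell, drug, shift))
}

.as_voltage_trace <- function(res, protocol = NULL, dt = NA, mode = "free") {
  vt <- data.frame(t = res$t, V = res$V, J_nav = res$J_nav,
                   J_kir = res$J_kir, J_chr = res$J_chr,
                   J_kv43 = res$J_kv43, J_leak = res$J_leak,
                   B = res$B, light = res$light, m = res$m, h = res$h)
  structure(list(data = vt,
                 stim_onsets = if (!is.null(protocol)) protocol$stim_onsets,
                 dt = dt, mode = mode),
            class = "voltage_trace")
}

#' Free-running (current-clamp-like) simulation
#'
#' Integrates the capacitance-normalised membrane equation
#' `dV/dt = -(J_nav + J_kir + J_chr + J_kv43 + J_leak)` (pA/pF = mV/ms)
#' under a blue-light protocol, with a fixed step `dt` (exponential-Euler
#' gating updates, explicit Euler for the voltage).  The initial state is
#' the dark resting steady state unless `init_v` is given.
#'
#' @param light A [light_protocol()].
#' @param cell A [cell_params()] object.
#' @param drug A [drug_model()] or `NULL` (drug-free).
#' @param conditions An [ionic_conditions()] object.
#' @param dt Integration step (ms); must be <= 0.02 ms for stability of the
#'   sub-millisecond NaV activation gating.
#' @param duration Total simulated time (ms); defaults to the protocol span.
#' @param record_dt Sampling interval of the returned trace (ms); snapped to
#'   a multiple of `dt`.
#' @param init_v Initial voltage (mV); defaults to [resting_potential()].
#'
#' @return A `voltage_trace`: sampled voltage plus per-conductance current
#'   densities, blocked fraction, light, and the NaV gating variables.
#' @examples
#' vt <- simulate_free(pulse_train(1, 20, 50, 5), duration = 200)
#' max(vt$data$V)   # spike overshoot, > 0 mV
#' @export
simulate_free <- function(light, cell = default_cell(), drug = NULL,
                          conditions = ionic_conditions(),
                          dt = 0.01, duration = NULL, record_dt = 0.1,
                          init_v = NULL) {
  if (is.null(drug)) drug <- .no_drug()
  if (dt > 0.02) stop("dt must be <= 0.02 ms")
  if (is.null(duration)) duration <- protocol_span(light)
  if (duration <= 0) stop("duration must be positive")
  seg <- light$segments
  if (sum(seg$duration_ms) < duration) {   # pad with darkness
    seg <- rbind(seg, data.frame(duration_ms = duration - sum(seg$duration_ms),
                                 intensity = 0))
  }
  if (is.null(init_v)) init_v <- resting_potential(cell, drug, conditions)
  # protocols begin after prolonged darkness: actuator closed at t = 0
  init <- .init_state(init_v, 0, cell, drug, conditions)
  rec <- max(1L, as.integer(round(record_dt / dt)))
  res <- .sim_core(seg$duration_ms, seg$intensity,
                   numeric(0), numeric(0),
                   .pack_params(cell, drug, conditions), FALSE,
                   dt, rec, duration, unname(init))
  .as_voltage_trace(res, light, dt, "free")
}

#' Voltage-clamp simulation
#'
#' Forces the membrane voltage to a piecewise-constant command waveform and
#' returns the total and per-conductance current densities.  An optional
#' light protocol may run concurrently (used to measure photocurrents under
#' clamp); otherwise the actuator stays closed.
#'
#' @param command A two-column data.frame or matrix `(duration_ms, mV)`
#'   describing the piecewise-constant command voltage.
#' @param cell,drug,conditions,dt,record_dt As in [simulate_free()].
#' @param light Optional [light_protocol()] applied concurrently.
#' @return A `voltage_trace` (mode `"vclamp"`).
#' @examples
#' cmd <- rbind(c(50, -100), c(10, -20), c(20, -100))
#' vc <- simulate_voltage_clamp(cmd)
#' min(vc$data$J_nav)    # peak inward NaV current at the -20 mV step
#' @export
simulate_voltage_clamp <- function(command, cell = default_cell(),
                                   drug = NULL,
                                   conditions = ionic_conditions(),
                                   light = NULL, dt = 0.01, record_dt = 0.05) {
  if (is.null(drug)) drug <- .no_drug()
  cmd <- as.matrix(command)
  if (ncol(cmd) != 2) stop("command must have columns (duration_ms, mV)")
  if (any(cmd[, 1] <= 0)) stop("command durations must be positive")
  duration <- sum(cmd[, 1])
  if (is.null(light)) {
    lseg <- data.frame(duration_ms = duration, intensity = 0)
  } else {
    lseg <- light$segments
    if (sum(lseg$duration_ms) < duration)
      lseg <- rbind(lseg,
                    data.frame(duration_ms = duration - sum(lseg$duration_ms),
                               intensity = 0))
  }
  v0 <- cmd[1, 2]
  init <- .init_state(v0, 0, cell, drug, conditions)
  rec <- max(1L, as.integer(round(record_dt / dt)))
  res <- .sim_core(lseg$duration_ms, lseg$intensity,
                   cmd[, 1], cmd[, 2],
                   .pack_params(cell, drug, conditions), TRUE,
                   dt, rec, duration, unname(init))
  .as_voltage_trace(res, light, dt, "vclamp")
}

#' @export
print.voltage_trace <- function(x, ...) {
  d <- x$data
  cat(sprintf("Voltage trace (%s): %d samples over %.1f ms, V in [%.1f, %.1f] mV\n",
              x$mode, nrow(d), max(d$t), min(d$V), max(d$V)))
  invisible(x)
}

#' @export
plot.voltage_trace <- function(x, ...) {
  graphics::plot(x$data$t, x$data$V, type = "l", xlab = "time (ms)",
                 ylab = "V (mV)", ...)
  if (length(x$stim_onsets))
    graphics::abline(v = x$stim_onsets, col = "skyblue", lty = 3)
  invisible(x)
}
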