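## Steady-state current-density functions and gating curves.  These are the
## same expressions the compiled integrator evaluates; they are exposed so
## calibration targets and tests can probe single conductances directly.

boltz_up <- function(v, vhalf, slope) 1 / (1 + exp((vhalf - v) / slope))
boltz_down <- function(v, vhalf, slope) 1 / (1 + exp((v - vhalf) / slope))
tau_bell <- function(v, d) d[1] + d[2] * exp(-((v - d[3]) / d[4])^2)
# two-sided bell (width below / above the peak)
tau_bell2 <- function(v, d) {
  w <- ifelse(v < d[3], d[4], d[5])
  d[1] + d[2] * exp(-((v - d[3]) / w)^2)
}

#' NaV fast-inactivation time constant
#'
#' The voltage-dependent inactivation time constant of the model (ms): a
#' two-sided bell that is slow near the inactivation midpoint and fast at
#' depolarised potentials; its value at -100 mV sets the repriming speed
#' (4.5 ms half-recovery for the calibrated cell).
#'
#' @param v Membrane voltage (mV); vectorised.
#' @param cell A [cell_params()] object.
#' @return Time constant (ms).
#' @export
nav_tau_h <- function(v, cell = default_cell()) tau_bell2(v, cell$nav_tau_h)

#' NaV steady-state gating curves
#'
#' Boltzmann steady-state activation (`nav_m_inf`) and fast inactivation
#' (`nav_h_inf`) of the model sodium conductance.
#'
#' @param v Membrane voltage (mV); vectorised.
#' @param cell A [cell_params()] object.
#' @param inact_shift Shift applied to the inactivation midpoint (mV), as
#'   produced by a `gating_shift` drug.
#' @return Open/available fraction in \[0, 1\].
#' @export
nav_m_inf <- function(v, cell = default_cell()) {
  boltz_up(v, cell$nav_act_vhalf, cell$nav_act_slope)
}

#' @rdname nav_m_inf
#' @export
nav_h_inf <- function(v, cell = default_cell(), inact_shift = 0) {
  boltz_down(v, cell$nav_inact_vhalf + inact_shift, cell$nav_inact_slope)
}

#' Channelrhodopsin photocurrent density
#'
#' Steady-state current density of the light-gated conductance:
#' `g_chr * p_open * rect(V) * (V - e_chr)`, where the open fraction at a
#' given light level saturates hyperbolically, `p = L / (L + EPD50)`, and
#' `rect(V)` is a Boltzmann factor suppressing outward current (inward
#' rectification).  The current is zero at the reversal potential and, with
#' the calibrated default cell, reaches -13.0 pA/pF at -60 mV under
#' saturating light.
#'
#' @param v Membrane voltage (mV).
#' @param light Blue-light power density (mW/cm^2), non-negative.
#' @param p_open Open fraction; defaults to the steady state for `light`.
#' @param cell A [cell_params()] object.
#' @return Current density (pA/pF); negative = inward.
#' @examples
#' cheriff_current(4, 100)        # zero at the reversal potential
#' cheriff_current(-60, 1e6)      # saturating: -13.0 pA/pF
#' @export
cheriff_current <- function(v, light, p_open = NULL, cell = default_cell()) {
  if (any(light < 0)) stop("light must be non-negative")
  if (is.null(p_open)) p_open <- light / (light + cell$chr_epd50)
  rect <- boltz_down(v, cell$chr_rect_vhalf, cell$chr_rect_slope)
  cell$g_chr * p_open * rect * (v - cell$e_chr)
}

#' Inward-rectifier K+ current density
#'
#' `g_kir * f(V - E_K) * (V - E_K)` with rectification factor
#' `f(dv) = 1 / (1 + exp((dv - vhalf) / slope))`: zero at E_K, ohmic inward
#' below E_K, outward conductance suppressed with depolarisation.
#'
#' @param v Membrane voltage (mV).
#' @param conditions An [ionic_conditions()] object (sets E_K).
#' @param cell A [cell_params()] object.
#' @return Current density (pA/pF).
#' @export
kir_current <- function(v, conditions = ionic_conditions(),
                        cell = default_cell()) {
  ek <- nernst_potential(conditions$k_out, conditions$k_in,
                         conditions$temperature, 1)
  f <- boltz_down(v - ek, cell$kir_rect_vhalf, cell$kir_rect_slope)
  cell$g_kir * f * (v - ek)
}

#' Instantaneous NaV current density
#'
#' `g_nav * m^3 * h * (1 - B) * (V - E_Na)` for explicit gating-state and
#' blocked-fraction values.  For a `tonic` drug the blocked fraction is the
#' resting equilibrium occupancy `C / (C + Kd)` unless `B` is supplied.
#'
#' @param v Membrane voltage (mV).
#' @param m,h Activation / inactivation gating variables in \[0, 1\].
#' @param drug A [drug_model()] (or `NULL` for drug-free).
#' @param B Blocked fraction in \[0, 1\]; defaults to 0 (`none`,
#'   `state_dependent` at rest, `gating_shift`) or the resting tonic
#'   occupancy for `tonic` drugs.
#' @param conditions An [ionic_conditions()] object (sets E_Na).
#' @param cell A [cell_params()] object.
#' @return Current density (pA/pF).
#' @export
nav_current <- function(v, m, h, drug = NULL, B = NULL,
                        conditions = ionic_conditions(),
                        cell = default_cell()) {
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  if (is.null(B)) {
    B <- if (!is.null(drug) && drug$scheme == "tonic")
      drug$concentration / (drug$concentration + drug$kd_rest) else 0
  }
  if (any(B < 0 | B > 1)) stop("blocked fraction must lie in [0, 1]")
  ena <- nernst_potential(conditions$na_out, conditions$na_in,
                          conditions$temperature, 1)
  cell$g_nav * m^3 * h * (1 - B) * (v - ena)
}

#' One guarded-receptor update of the blocked fraction
#'
#' Advances `dB/dt = k_on*C*(1-B)*f_I - k_off*B` by `dt` milliseconds using
#' the exact exponential update at frozen voltage, where
#' `f_I = 1 - h_inf(V)` weighted by the drug's `state_preference`.
#' This is the reference (R-level) implementation of the update rule used
#' inside the compiled integrator.
#'
#' @param B Current blocked fraction in \[0, 1\].
#' @param v Membrane voltage (mV), held fixed over the step.
#' @param drug A `state_dependent` [drug_model()].
#' @param dt Step length (ms), positive.
#' @param cell A [cell_params()] object.
#' @return Updated blocked fraction.
#' @export
drug_block_step <- function(B, v, drug, dt, cell = default_cell()) {
  stopifnot(dt > 0, B >= 0, B <= 1)
  f_i <- 1 - nav_h_inf(v, cell)
  f_bind <- drug$state_preference * f_i + (1 - drug$state_preference)
  alpha <- drug$k_on * drug$concentration * f_bind / 1000   # ms^-1
  beta <- drug$k_off / 1000
  rate <- alpha + beta
  if (rate == 0) return(B)
  binf <- alpha / rate
  pmin(1, pmax(0, binf + (B - binf) * exp(-dt * rate)))
}
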