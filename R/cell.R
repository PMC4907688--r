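#' Model-cell parameters
#'
#' Conductance densities and gating descriptors for the single-compartment
#' spiking-HEK model.  All conductance densities are capacitance-normalised
#' (nS/pF, i.e. pA/pF of current per mV of driving force); voltages are mV
#' and time constants ms.  The defaults are the package's calibrated
#' "reference cell": the channelrhodopsin conductance reproduces a
#' saturating steady-state photocurrent of -13.0 pA/pF at -60 mV with an
#' EPD50 of 20 mW/cm^2 and a +4 mV reversal; the sodium conductance gives a
#' peak current density of -61.4 pA/pF at a -20 mV step from -100 mV and
#' half-recovery from fast inactivation in 4.5 ms at -100 mV; the leak is
#' balanced so the dark resting potential in a 2 mM K+ bath is -97.2 mV.
#'
#' Gating time constants use a bell-shaped voltage dependence
#' `tau(V) = base + amp * exp(-((V - vpeak)/width)^2)`; the inactivation
#' time constant uses different widths below and above its peak so that
#' inactivation onset is slow near the midpoint (tens of ms) but fast at
#' depolarised potentials, while recovery at -100 mV matches the observed
#' repriming kinetics.
#'
#' @param g_nav NaV maximal conductance density (nS/pF).
#' @param nav_act_vhalf,nav_act_slope Activation midpoint / slope (mV).
#' @param nav_inact_vhalf,nav_inact_slope Fast-inactivation midpoint / slope (mV).
#' @param nav_tau_m Length-4 numeric `(base, amp, vpeak, width)` describing
#'   the bell-shaped activation time constant (ms, mV).
#' @param nav_tau_h Length-5 numeric `(base, amp, vpeak, width_below,
#'   width_above)`: a two-sided bell, slow around the inactivation midpoint
#'   and fast at depolarised potentials, anchored so the repriming time
#'   constant at -100 mV is 4.5/ln(2) ms.
#' @param g_kir Inward-rectifier K+ conductance density (nS/pF).
#' @param kir_rect_vhalf,kir_rect_slope Rectification Boltzmann midpoint /
#'   slope, expressed relative to E_K (mV).
#' @param g_chr Channelrhodopsin conductance density (nS/pF).
#' @param e_chr Channelrhodopsin reversal potential (mV).
#' @param chr_epd50 Effective light power density for half-maximal
#'   photocurrent (mW/cm^2).
#' @param chr_tau_on,chr_tau_off Opening / closing time constants (ms).
#' @param chr_rect_vhalf,chr_rect_slope Inward-rectification Boltzmann of the
#'   photocurrent (mV).
#' @param g_kv43 Kv4.3 maximal conductance density (nS/pF); 0 disables the
#'   conductance (the default cell does not express it).
#' @param kv43_act_vhalf,kv43_act_slope Kv4.3 activation Boltzmann (mV).
#' @param kv43_tau_act Kv4.3 activation time constant (ms).
#' @param kv43_inact_vhalf,kv43_inact_slope Kv4.3 inactivation Boltzmann (mV).
#' @param kv43_tau_fast,kv43_tau_slow Fast / slow inactivation time
#'   constants (ms); `kv43_tau_fast < kv43_tau_slow`.
#' @param kv43_frac_fast Weight of the fast inactivation component in \[0, 1\].
#' @param kv43_tau_deact Deactivation time constant of the activation gate
#'   on repolarisation (ms).
#' @param g_leak Ohmic leak conductance density (nS/pF).
#' @param e_leak Leak reversal potential (mV).
#'
#' @return An object of class `cell_params`.
#' @seealso [default_cell()], [simulate_free()], [simulate_voltage_clamp()]
#' @export
cell_params <- function(g_nav = 1.15757107,
                        nav_act_vhalf = -58, nav_act_slope = 13,
                        nav_inact_vhalf = -78, nav_inact_slope = 7,
                        nav_tau_m = c(0.15, 0.1, -40, 30),
                        nav_tau_h = c(1.0, 10.9985141, -75, 30, 45),
                        g_kir = 0.62, kir_rect_vhalf = 45, kir_rect_slope = 20,
                        g_chr = 0.20684536, e_chr = 4, chr_epd50 = 20,
                        chr_tau_on = 5, chr_tau_off = 15,
                        chr_rect_vhalf = 20, chr_rect_slope = 20,
                        g_kv43 = 0,
                        kv43_act_vhalf = -15, kv43_act_slope = 13,
                        kv43_tau_act = 0.69,
                        kv43_inact_vhalf = -50, kv43_inact_slope = 6,
                        kv43_tau_fast = 51, kv43_tau_slow = 352,
                        kv43_frac_fast = 0.6, kv43_tau_deact = 15,
                        g_leak = 0.06023470, e_leak = 0) {
  p <- list(g_nav = g_nav,
            nav_act_vhalf = nav_act_vhalf, nav_act_slope = nav_act_slope,
            nav_inact_vhalf = nav_inact_vhalf, nav_inact_slope = nav_inact_slope,
            nav_tau_m = as.numeric(nav_tau_m), nav_tau_h = as.numeric(nav_tau_h),
            g_kir = g_kir, kir_rect_vhalf = kir_rect_vhalf,
            kir_rect_slope = kir_rect_slope,
            g_chr = g_chr, e_chr = e_chr, chr_epd50 = chr_epd50,
            chr_tau_on = chr_tau_on, chr_tau_off = chr_tau_off,
            chr_rect_vhalf = chr_rect_vhalf, chr_rect_slope = chr_rect_slope,
            g_kv43 = g_kv43,
            kv43_act_vhalf = kv43_act_vhalf, kv43_act_slope = kv43_act_slope,
            kv43_tau_act = kv43_tau_act,
            kv43_inact_vhalf = kv43_inact_vhalf,
            kv43_inact_slope = kv43_inact_slope,
            kv43_tau_fast = kv43_tau_fast, kv43_tau_slow = kv43_tau_slow,
            kv43_frac_fast = kv43_frac_fast, kv43_tau_deact = kv43_tau_deact,
            g_leak = g_leak, e_leak = e_leak)
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

validate_cell_params <- function(p) {
  dens <- c(p$g_nav, p$g_kir, p$g_chr, p$g_kv43, p$g_leak)
  if (any(!is.finite(dens)) || any(dens < 0))
    stop("conductance densities must be finite and non-negative")
  slopes <- c(p$nav_act_slope, p$nav_inact_slope, p$kir_rect_slope,
              p$chr_rect_slope, p$kv43_act_slope, p$kv43_inact_slope)
  if (any(slopes == 0)) stop("Boltzmann slopes must be nonzero")
  if (p$chr_epd50 <= 0) stop("chr_epd50 must be positive")
  if (length(p$nav_tau_m) != 4L)
    stop("nav_tau_m must be length-4 (base, amp, vpeak, width)")
  if (length(p$nav_tau_h) != 5L)
    stop("nav_tau_h must be length-5 (base, amp, vpeak, width_below, width_above)")
  if (p$nav_tau_m[1] <= 0 || p$nav_tau_h[1] <= 0)
    stop("gating time-constant floors must be positive")
  if (p$kv43_tau_fast >= p$kv43_tau_slow)
    stop("kv43_tau_fast must be smaller than kv43_tau_slow")
  if (p$kv43_frac_fast < 0 || p$kv43_frac_fast > 1)
    stop("kv43_frac_fast must lie in [0, 1]")
  invisible(p)
}

#' The calibrated reference cell
#'
#' Returns the default parameter set (see [cell_params()]), optionally with
#' the Kv4.3 conductance enabled, which turns the broad plateau action
#' potential into a notched waveform (fast transient repolarisation followed
#' by recovery toward the light-driven plateau).
#'
#' @param kv43 Logical; enable the Kv4.3 conductance.
#' @return A `cell_params` object.
#' @export
default_cell <- function(kv43 = FALSE) {
  if (kv43) cell_params(g_kv43 = 1.72) else cell_params()
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Spiking-HEK cell parameters (capacitance-normalised)\n")
  cat(sprintf("  NaV : g = %.4g nS/pF, act V1/2 %g mV (k %g), inact V1/2 %g mV (k %g)\n",
              x$g_nav, x$nav_act_vhalf, x$nav_act_slope,
              x$nav_inact_vhalf, x$nav_inact_slope))
  cat(sprintf("  Kir : g = %.4g nS/pF, rectification V1/2 %g mV rel. E_K\n",
              x$g_kir, x$kir_rect_vhalf))
  cat(sprintf("  ChR : g = %.4g nS/pF, E_rev %g mV, EPD50 %g mW/cm^2\n",
              x$g_chr, x$e_chr, x$chr_epd50))
  if (x$g_kv43 > 0)
    cat(sprintf("  Kv4.3: g = %.4g nS/pF, tau_act %g ms, tau_inact %g/%g ms\n",
                x$g_kv43, x$kv43_tau_act, x$kv43_tau_fast, x$kv43_tau_slow))
  cat(sprintf("  leak: g = %.4g nS/pF, E %g mV\n", x$g_leak, x$e_leak))
  invisible(x)
}

#' Drug model acting on the sodium conductance
#'
#' Phenomenological description of sodium-channel block.  Four schemes are
#' supported:
#' \describe{
#'   \item{`none`}{inert compound (vehicle).}
#'   \item{`tonic`}{near-instantaneous equilibrium occupancy
#'     `B = C / (C + Kd)`, with a weak (2x) affinity increase for the
#'     inactivated state; the occupancy relaxes on a slow time scale
#'     (seconds), so it is effectively set by the holding/resting state.}
#'   \item{`state_dependent`}{guarded-receptor kinetics
#'     `dB/dt = k_on * C * (1 - B) * f_I - k_off * B`, where
#'     `f_I = 1 - h_inf(V)` is the smooth voltage surrogate for
#'     inactivated-state availability.  Blocked channels neither conduct
#'     nor reprime until unbound.  Slow `k_off` gives monotone use-dependent
#'     block; fast `k_off` gives alternans.}
#'   \item{`gating_shift`}{shifts the NaV fast-inactivation midpoint by
#'     `inact_shift` mV without touching activation.}
#' }
#'
#' @param name Compound label.
#' @param scheme One of `"none"`, `"tonic"`, `"state_dependent"`,
#'   `"gating_shift"`.
#' @param concentration Concentration (uM), non-negative.
#' @param k_on Binding rate constant ((uM s)^-1), `state_dependent` scheme.
#' @param k_off Unbinding rate constant (s^-1), `state_dependent` scheme.
#' @param kd_rest Resting-state dissociation constant (uM), `tonic` scheme.
#' @param inact_shift Shift of the inactivation midpoint (mV, usually
#'   negative), `gating_shift` scheme.
#' @param state_preference Fraction of the binding rate gated by the
#'   inactivated state (1 = pure inactivated-state binding).
#' @param tonic_tau Relaxation time of the tonic occupancy (ms).
#'
#' @return An object of class `drug_model`.
#' @seealso [drug_preset()]
#' @export
drug_model <- function(name = "compound",
                       scheme = c("none", "tonic", "state_dependent",
                                  "gating_shift"),
                       concentration = 0,
                       k_on = 0, k_off = 0, kd_rest = Inf,
                       inact_shift = 0, state_preference = 1,
                       tonic_tau = 5000) {
  scheme <- match.arg(scheme)
  if (concentration < 0) stop("concentration must be non-negative")
  if (k_on < 0 || k_off < 0) stop("rate constants must be non-negative")
  if (scheme == "tonic" && !(kd_rest > 0)) stop("kd_rest must be positive")
  if (state_preference < 0 || state_preference > 1)
    stop("state_preference must lie in [0, 1]")
  structure(list(name = name, scheme = scheme,
                 concentration = concentration,
                 k_on = k_on, k_off = k_off, kd_rest = kd_rest,
                 inact_shift = inact_shift,
                 state_preference = state_preference,
                 tonic_tau = tonic_tau),
            class = "drug_model")
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("Drug model '%s': scheme %s, %g uM", x$name, x$scheme,
              x$concentration))
  if (x$scheme == "state_dependent")
    cat(sprintf(", k_on %g (uM s)^-1, k_off %g s^-1", x$k_on, x$k_off))
  if (x$scheme == "tonic") cat(sprintf(", Kd(rest) %g uM", x$kd_rest))
  if (x$scheme == "gating_shift")
    cat(sprintf(", inactivation shift %g mV", x$inact_shift))
  cat("\n")
  invisible(x)
}

#' Canonical drug phenotypes
#'
#' Named parameter sets for the pharmacological phenotypes the simulator is
#' calibrated to emulate:
#' \describe{
#'   \item{`dmso`}{vehicle, inert.}
#'   \item{`ttx`}{tonic pore blocker with weak state dependence
#'     (Kd(rest) = 0.126 uM).}
#'   \item{`lidocaine`}{use-dependent blocker of intermediate kinetics;
#'     at 200 uM it spares 2 Hz trains but suppresses spiking at 4-8 Hz.}
#'   \item{`amitriptyline`}{slow-unbinding use-dependent blocker; at 3 uM
#'     the optical repriming assay gives a half-recovery of 280 ms, and at
#'     10 uM voltage-clamp recovery stays below 50 percent out to 256 ms.}
#'   \item{`alternans`}{fast-unbinding use-dependent blocker
#'     (isradipine/iloperidone-like); voltage-clamp half-recovery of
#'     20 ms with elevated spike-amplitude dispersion at 10 Hz.}
#'   \item{`carbamazepine`}{inactivation-curve shifter (-15 mV).}
#' }
#'
#' @param name Preset name (see Details).
#' @param concentration Concentration in uM (defaults to the concentration
#'   the phenotype is described at).
#' @return A `drug_model` object.
#' @export
drug_preset <- function(name = c("dmso", "ttx", "lidocaine", "amitriptyline",
                                 "alternans", "carbamazepine"),
                        concentration = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    dmso = list(scheme = "none", conc = 0),
    ttx = list(scheme = "tonic", conc = 0.126, kd_rest = 0.126),
    lidocaine = list(scheme = "state_dependent", conc = 200,
                     k_on = 0.12, k_off = 3),
    amitriptyline = list(scheme = "state_dependent", conc = 10,
                         k_on = 1, k_off = 0.821),
    alternans = list(scheme = "state_dependent", conc = 10,
                     k_on = 3, k_off = 14.11),
    carbamazepine = list(scheme = "gating_shift", conc = 100,
                         inact_shift = -15))
  if (is.null(concentration)) concentration <- def$conc
  drug_model(name = name, scheme = def$scheme, concentration = concentration,
             k_on = def$k_on %||% 0, k_off = def$k_off %||% 0,
             kd_rest = def$kd_rest %||% Inf,
             inact_shift = def$inact_shift %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
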