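# Calibrated reference parameters of the optically excitable spiking-HEK model cell.
# Conductance densities in nS/pF, voltages in mV, times in ms, light in mW/cm^2.
# Calibration anchors (all reproduced by the simulator with these values):
#   g_chr, chr_epd50, e_chr      -> saturating photocurrent -13.0 pA/pF at -60 mV,
#                                   EPD50 20 mW/cm^2, reversal +4 mV
#   g_nav + gating descriptors   -> peak step-evoked current -61.4 pA/pF at -20 mV
#                                   (holding -100 mV); repriming half-time 4.5 ms
#   g_kir, g_leak                -> dark resting potential -97.2 mV in 2 mM K+ bath,
#                                   near-Nernstian resting potential vs bath K+
#   nav_tau_h                    -> two-sided bell; value at -100 mV = 4.5/ln 2 ms

g_nav: 1.15757107
nav_act_vhalf: -58
nav_act_slope: 13
nav_inact_vhalf: -78
nav_inact_slope: 7
nav_tau_m:   0.15,  0.10,-40.00, 30.00
nav_tau_h:   1.0000000, 10.9985141,-75.0000000, 30.0000000, 45.0000000
g_kir: 0.62
kir_rect_vhalf: 45
kir_rect_slope: 20
g_chr: 0.20684536
e_chr: 4
chr_epd50: 20
chr_tau_on: 5
chr_tau_off: 15
chr_rect_vhalf: 20
chr_rect_slope: 20
g_kv43: 0
kv43_act_vhalf: -5
kv43_act_slope: 13
kv43_tau_act: 0.69
kv43_inact_vhalf: -50
kv43_inact_slope: 6
kv43_tau_fast: 51
kv43_tau_slow: 352
kv43_frac_fast: 0.6
g_leak: 0.0602347
e_leak: 0
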