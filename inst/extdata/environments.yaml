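# Sodium environment relaxation parameters (spectral densities in s^-1,
# residual quadrupole splitting in Hz).
#
# DERIVED CALIBRATION: these values are not tissue measurements.  They were
# fit once (multi-start minimax over the three preset sequences) so that the
# simulated steady-state relaxation weightings reproduce the reference
# per-compartment weightings of the contrast model (see table2_weightings()
# and the package vignette).  Intra- and extracellular parameters are
# identical by construction.  The intra/extra and myelin rows reproduce
# their reference weightings to better than 0.001; the edema row is a
# compromise (best attainable ~ +/-0.06, see vignette), and the agar row is
# calibrated against the measured control-WM/agar intensity ratio of the
# density-weighted sequence.
environments:
  intra:
    J0: 182.080
    J1: 145.389
    J2: 10.008
    fQ_hz: 0.0
    fQ_model: single-value
  extra:
    J0: 182.080
    J1: 145.389
    J2: 10.008
    fQ_hz: 0.0
    fQ_model: single-value
  myelin:
    J0: 1858.025
    J1: 17.104
    J2: 14.017
    fQ_hz: 465.28
    fQ_model: single-value
  edema:
    J0: 10.103
    J1: 10.103
    J2: 10.103
    fQ_hz: 0.0
    fQ_model: single-value
  csf:
    J0: 7.171
    J1: 7.171
    J2: 7.171
    fQ_hz: 0.0
    fQ_model: single-value
  agar:
    J0: 258.260
    J1: 258.193
    J2: 5.572
    fQ_hz: 0.0
    fQ_model: single-value
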