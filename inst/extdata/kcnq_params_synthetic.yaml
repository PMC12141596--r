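# Default channel kinetics shipped with kcnqres.
#
# SYNTHETIC RECONSTRUCTION: the activation gate (m) follows the published
# lineage of globus-pallidus KCNQ kinetics (Boltzmann midpoint -61 mV,
# slope 19.5 mV, double-sigmoid time constant 6.7..100 ms, fourth-power
# gate); the rapid-inactivation gate (h) is an ERG-like parameter set
# constructed for this package so that the kcnq_inactivation model expresses
# rapid inactivation and recovery (millisecond-scale tau_h), an opposing
# conductance transient at voltage steps, and depolarization-evoked membrane
# potential oscillation.  See the methods vignette for the rationale.
#
# Units are encoded in the key names (mV, ms, S/cm^2).

kcnq:
  gmax_S_cm2: 0.001
  m:
    theta_mV: -61.0
    k_mV: 19.5
    tau0_ms: 6.7
    tau1_ms: 100.0
    phi_mV: -61.0
    sigma0_mV: 35.0
    sigma1_mV: -25.0
    floor: 0.0
    exponent: 4

kcnq_inactivation:
  gmax_S_cm2: 0.001
  m:
    theta_mV: -61.0
    k_mV: 19.5
    tau0_ms: 6.7
    tau1_ms: 100.0
    phi_mV: -61.0
    sigma0_mV: 35.0
    sigma1_mV: -25.0
    floor: 0.0
    exponent: 4
  h:
    theta_mV: -25.0
    k_mV: -6.0
    tau0_ms: 1.5
    tau1_ms: 8.0
    phi_mV: -25.0
    sigma0_mV: 15.0
    sigma1_mV: -15.0
    floor: 0.38
    exponent: 1
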