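# Voltage-step conductance metrics for the rapidly inactivating variant:
# opposing transients at onset and offset.
type: vstep
label: KCNQ_inactivation +10 mV step from -30 mV
channel: kcnq_inactivation
protocol:
  holding_mV: -30
  step_mV: -20
seed: 1
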