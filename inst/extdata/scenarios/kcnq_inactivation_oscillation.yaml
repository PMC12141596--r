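# Depolarizing current step on the inactivating cell: sustained oscillation.
type: oscillation
label: KCNQ_inactivation current step to -25 mV plateau
channel: kcnq_inactivation
protocol:
  target_mV: -25
seed: 1
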