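# Depolarizing current step on the plain KCNQ cell: no oscillation.
type: oscillation
label: KCNQ current step to -25 mV plateau
channel: kcnq
protocol:
  target_mV: -25
seed: 1
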