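# Passive control: ZAP impedance of the cell with no voltage-gated channels.
type: zap
label: passive control ZAP
channel: none
protocol:
  holding_mV: -60
seed: 1
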