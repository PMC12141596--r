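# ZAP impedance of the KCNQ model cell at a depolarized holding potential.
type: zap
label: KCNQ ZAP at -40 mV
channel: kcnq
protocol:
  holding_mV: -40
seed: 1
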