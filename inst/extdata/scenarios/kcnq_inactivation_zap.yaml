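# ZAP impedance of the rapidly inactivating KCNQ variant at -40 mV.
type: zap
label: KCNQ_inactivation ZAP at -40 mV
channel: kcnq_inactivation
protocol:
  holding_mV: -40
seed: 1
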