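# Reference RLC circuit: leaky-inductor current under a 10 mV step.
type: rlc_step
label: RLC leaky inductor step response
seed: 1
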