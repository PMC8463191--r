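h: 1.8 1.5 1.0 4.0 3.0 0.6 2.0 10.0 0.2
eps: -0.35 -3.40 -2.00 -5.00
tau: 26.0 32.5 2.6 2.6
a: 2.8
b: 0.5
eps_sigmoid: 250000
intermodule_scale: 6
topology: bidirectional
cross_inside_tau: FALSE
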