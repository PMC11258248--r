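format: carotdyn-model/1
id: avoided_crossing_1d
form: avoided_crossing
states: 2
dof: 1
labels:
- S0
- S1
masses: 1.0971598
params:
- 0.2721139
- 3.0235618
- 0.1360569
- 3.5710648
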