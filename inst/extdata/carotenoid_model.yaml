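format: carotdyn-model/1
id: carotenoid_s-trans
form: carotenoid
states: 3
dof: 2
labels:
- S0
- S1
- S2
masses:
- 10.0
- 50.0
params:
- 30.0
- 0.1
- 15.0
- 1.9
- 25.0
- 0.2
- 2.3
- 2.0
- 0.8
- 1.5
- 0.2
- 0.02
- 1.0
- 0.05
- 0.01
dipole:
- 0.0
- 0.05
- 1.0
- 0.05
- 0.0
- 0.6
- 1.0
- 0.6
- 0.0
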