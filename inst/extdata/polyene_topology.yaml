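format: carotdyn-topology/1
single_bonds:
- 2
- 3
- 4
- 5
- 6
- 7
- 8
- 9
- 10
- 11
- 12
- 13
- 14
- 15
- 16
- 17
- 18
- 19
- 20
- 21
double_bonds:
- 1
- 2
- 3
- 4
- 5
- 6
- 7
- 8
- 9
- 10
- 11
- 12
- 13
- 14
- 15
- 16
- 17
- 18
- 19
- 20
- 21
- 22
dihedrals_s:
  ds1:
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  ds2:
  - 3.0
  - 4.0
  - 5.0
  - 6.0
  ds3:
  - 5.0
  - 6.0
  - 7.0
  - 8.0
  ds4:
  - 7.0
  - 8.0
  - 9.0
  - 10.0
  ds5:
  - 9.0
  - 10.0
  - 11.0
  - 12.0
  ds6:
  - 11.0
  - 12.0
  - 13.0
  - 14.0
  ds7:
  - 13.0
  - 14.0
  - 15.0
  - 16.0
  ds8:
  - 15.0
  - 16.0
  - 17.0
  - 18.0
  ds9:
  - 17.0
  - 18.0
  - 19.0
  - 20.0
dihedrals_d:
  dd1:
  - 2.0
  - 3.0
  - 4.0
  - 5.0
  dd2:
  - 4.0
  - 5.0
  - 6.0
  - 7.0
  dd3:
  - 6.0
  - 7.0
  - 8.0
  - 9.0
  dd4:
  - 8.0
  - 9.0
  - 10.0
  - 11.0
  dd5:
  - 10.0
  - 11.0
  - 12.0
  - 13.0
  dd6:
  - 12.0
  - 13.0
  - 14.0
  - 15.0
  dd7:
  - 14.0
  - 15.0
  - 16.0
  - 17.0
  dd8:
  - 16.0
  - 17.0
  - 18.0
  - 19.0
  dd9:
  - 18.0
  - 19.0
  - 20.0
  - 21.0
lumenal:
- dd1
- dd2
- dd3
- dd4
stromal:
- dd5
- dd6
- dd7
- dd8
- dd9
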