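"atom","x","y","z","q"
1,-4.30639084195718,22.1836716751568,0.884818299673498,-0.0307680670936015
2,3.17775198724121,27.8783634747379,0.304775098338723,0.0217821258276128
3,4.42621732363477,20.9785303962417,4.7763589094393,-0.0521553337521023
4,-2.30618123663589,27.0983046619222,-3.02350404672325,0.0124671871681443
5,-3.30651876749471,22.1782304323278,3.44225987326354,-0.0237556817338784
6,-4.6610437752679,22.6794359297492,-4.04972081072628,-0.0418314159822976
7,-3.21214995812625,25.0476795178838,-1.18848996702582,-0.00465298728175716
8,1.41665365546942,21.8858692678623,-4.54115878790617,-0.0679324714220338
9,-4.77122256532311,24.3942932505161,-3.47376161022112,-0.0177073728963427
10,-4.91675173398107,26.69819295872,2.74718186818063,0.0347656602791065
11,-1.07302802847698,22.4088323116302,-1.05413560755551,-0.0426260131138186
12,3.13880559289828,28.932648957707,-1.38486909214407,0.0290165109038571
13,-1.2375154462643,28.8275638688356,-0.789099554531276,0.0401241578832079
14,-1.19187816279009,28.1406325451098,-1.77988475654274,0.0276568705784653
15,-2.35081622377038,26.3326460821554,0.521608307026327,0.0159241374793236
16,-0.606656835880131,29.4108754466288,4.71265458269045,0.0663131663340004
17,-0.42392848758027,26.9391142437235,0.579603190999478,0.019316800412172
18,0.407075472176075,28.4370223898441,0.741449142806232,0.0369609269434157
19,1.65679829893634,23.8464446016587,1.41348162665963,-0.0216967398994968
20,-3.87301062466577,23.9112994633615,3.2394898426719,-0.0012014606339768
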