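"atom","x","y","z","q"
1,-4.45500411558896,-1.36211971985176,-1.70974194770679,-0.0149899700297494
2,-9.98963374178857,-1.49651616578922,3.63887825980783,-0.0627172303019362
3,0.212167459540069,-4.38011556165293,1.37789903208613,0.00922350113612709
4,-9.71904183272272,-0.169822494499385,-4.86219404498115,-0.0418245569726673
5,-8.70620446745306,-1.00856714416295,0.291648111306131,-0.0469712614249558
6,9.09698450937867,-4.83785422053188,3.34363039350137,0.0614986863591499
7,-8.27008217573166,-3.74916744651273,0.0285592349246144,-0.0420281016362009
8,-4.20049981679767,-1.01850557606667,0.977607655804604,-0.0198582737812822
9,7.61398345697671,0.0491762650199234,-0.744049290660769,0.05886541322972
10,-7.53567597363144,-1.72320641577244,-1.8779535125941,-0.0340248816836803
11,-6.49774154648185,-0.882203946821392,-2.7807277510874,-0.0257699243891756
12,-1.18499456439167,-2.97586965607479,-0.565737709403038,0.00408040465466325
13,8.14365947153419,3.12668203841895,-0.874759086873382,0.0608096282259763
14,7.02083733864129,1.42031987197697,3.15702560124919,0.0451712810235501
15,4.67974985484034,-2.23126692930236,-3.37341083213687,0.0476137073032927
16,1.47371442988515,-3.96443992853165,0.969833894632757,0.0179846102880219
17,-0.364689282141626,-2.43997245561332,-3.65265032276511,0.0162379446731522
18,-3.38778011035174,-4.42141051171347,2.52363343257457,-0.0163797389627097
19,-6.84679502155632,-2.52544142538682,-3.25916393427178,-0.0259456810116441
20,-0.39731893222779,-2.84988771192729,0.798331354744732,0.00583317418091487
21,-5.92574810609221,-0.0632623769342899,2.51312012318522,-0.0349900740008921
22,3.60734775196761,1.53446026844904,-3.17202452104539,0.0381813431203255
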