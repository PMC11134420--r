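label,x,y,z
Nz,0.000000000,90.000000000,0.000000000
NFpz,0.000000000,88.891950654,14.079101854
Fpz,0.000000000,85.595086467,27.811529494
AFpz,0.000000000,80.190587177,40.859144977
AFz,0.000000000,72.811529494,52.900672706
AFFz,0.000000000,63.639610307,63.639610307
Fz,0.000000000,52.900672706,72.811529494
FFCz,0.000000000,40.859144977,80.190587177
FCz,0.000000000,27.811529494,85.595086467
FCCz,0.000000000,14.079101854,88.891950654
Cz,0.000000000,0.000000000,90.000000000
CCPz,0.000000000,-14.079101854,88.891950654
CPz,0.000000000,-27.811529494,85.595086467
CPPz,0.000000000,-40.859144977,80.190587177
Pz,0.000000000,-52.900672706,72.811529494
PPOz,0.000000000,-63.639610307,63.639610307
POz,0.000000000,-72.811529494,52.900672706
POOz,0.000000000,-80.190587177,40.859144977
Oz,0.000000000,-85.595086467,27.811529494
OIz,0.000000000,-88.891950654,14.079101854
Iz,0.000000000,-90.000000000,0.000000000
T9,-90.000000000,0.000000000,0.000000000
T9h,-88.891950654,0.000000000,14.079101854
T7,-85.595086467,0.000000000,27.811529494
T7h,-80.190587177,0.000000000,40.859144977
C5,-72.811529494,0.000000000,52.900672706
C5h,-63.639610307,0.000000000,63.639610307
C3,-52.900672706,0.000000000,72.811529494
C3h,-40.859144977,0.000000000,80.190587177
C1,-27.811529494,0.000000000,85.595086467
C1h,-14.079101854,0.000000000,88.891950654
C2h,14.079101854,0.000000000,88.891950654
C2,27.811529494,0.000000000,85.595086467
C4h,40.859144977,0.000000000,80.190587177
C4,52.900672706,0.000000000,72.811529494
C6h,63.639610307,0.000000000,63.639610307
C6,72.811529494,0.000000000,52.900672706
T8h,80.190587177,0.000000000,40.859144977
T8,85.595086467,0.000000000,27.811529494
T10h,88.891950654,0.000000000,14.079101854
T10,90.000000000,0.000000000,0.000000000
Fp1,-26.450336353,81.405764747,27.811529494
AF7,-50.311529494,69.247879586,27.811529494
F7,-69.247879586,50.311529494,27.811529494
FT7,-81.405764747,26.450336353,27.811529494
TP7,-81.405764747,-26.450336353,27.811529494
P7,-69.247879586,-50.311529494,27.811529494
PO7,-50.311529494,-69.247879586,27.811529494
O1,-26.450336353,-81.405764747,27.811529494
Fp2,26.450336353,81.405764747,27.811529494
AF8,50.311529494,69.247879586,27.811529494
F8,69.247879586,50.311529494,27.811529494
FT8,81.405764747,26.450336353,27.811529494
TP8,81.405764747,-26.450336353,27.811529494
P8,69.247879586,-50.311529494,27.811529494
PO8,50.311529494,-69.247879586,27.811529494
O2,26.450336353,-81.405764747,27.811529494
F5,-57.663594694,51.370497903,46.216683050
F3,-41.312747699,52.196371374,60.570584386
F1,-21.546924954,52.720881927,69.686717772
F2,21.546924954,52.720881927,69.686717772
F4,41.312747699,52.196371374,60.570584386
F6,57.663594694,51.370497903,46.216683050
FC5,-68.920573632,27.001166661,51.194643559
FC3,-49.919161745,27.436622807,69.680047500
FC1,-26.198052073,27.715533800,81.520005236
FC2,26.198052073,27.715533800,81.520005236
FC4,49.919161745,27.436622807,69.680047500
FC6,68.920573632,27.001166661,51.194643559
CP5,-68.920573632,-27.001166661,51.194643559
CP3,-49.919161745,-27.436622807,69.680047500
CP1,-26.198052073,-27.715533800,81.520005236
CP2,26.198052073,-27.715533800,81.520005236
CP4,49.919161745,-27.436622807,69.680047500
CP6,68.920573632,-27.001166661,51.194643559
P5,-57.663594694,-51.370497903,46.216683050
P3,-41.312747699,-52.196371374,60.570584386
P1,-21.546924954,-52.720881927,69.686717772
P2,21.546924954,-52.720881927,69.686717772
P4,41.312747699,-52.196371374,60.570584386
P6,57.663594694,-51.370497903,46.216683050
AF3,-28.166534699,71.870312875,46.274230953
AF4,28.166534699,71.870312875,46.274230953
PO3,-28.166534699,-71.870312875,46.274230953
PO4,28.166534699,-71.870312875,46.274230953
Nasion,0.000000000,90.000000000,0.000000000
LPA,-90.000000000,0.000000000,0.000000000
RPA,90.000000000,0.000000000,0.000000000
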