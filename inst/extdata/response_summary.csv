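response,units,formulation_id,mean,sd,n
STIba,g,1,57.8,0.591,10
STIba,g,2,62.0,0.921,10
STIba,g,3,61.5,0.662,10
STIba,g,4,57.8,0.613,10
STIba,g,5,53.9,0.660,10
STIba,g,6,60.3,0.711,10
STIba,g,7,58.7,1.013,10
STIba,g,8,59.7,1.032,10
STIba,g,9,63.7,0.781,10
STIba,g,10,52.4,0.571,10
STIba,g,11,55.0,0.472,10
FIRba,g,1,2508,50.7,4
FIRba,g,2,2699,57.6,4
FIRba,g,3,2202,38.5,4
FIRba,g,4,2259,110,4
FIRba,g,5,2905,165,4
FIRba,g,6,2595,75.7,4
FIRba,g,7,2346,80.6,4
FIRba,g,8,2170,45.1,4
FIRba,g,9,2177,111,4
FIRba,g,10,2623,37.8,4
FIRba,g,11,2988,116,4
SVO,mL/g,1,2.69,0.09,NA
SVO,mL/g,2,2.43,0.05,NA
SVO,mL/g,3,2.41,0.01,NA
SVO,mL/g,4,2.85,0.08,NA
SVO,mL/g,5,2.83,0.07,NA
SVO,mL/g,6,2.58,0.06,NA
SVO,mL/g,7,2.70,0.01,NA
SVO,mL/g,8,2.65,0.03,NA
SVO,mL/g,9,2.47,0.09,NA
SVO,mL/g,10,2.92,0.01,NA
SVO,mL/g,11,2.63,0.08,NA
BLO,%,1,13.6,0.135,NA
BLO,%,2,14.6,0.393,NA
BLO,%,3,15.0,0.310,NA
BLO,%,4,13.1,0.321,NA
BLO,%,5,12.7,0.173,NA
BLO,%,6,12.9,0.204,NA
BLO,%,7,13.6,0.211,NA
BLO,%,8,14.1,1.139,NA
BLO,%,9,14.9,0.588,NA
BLO,%,10,11.9,0.239,NA
BLO,%,11,13.3,0.258,NA
aw,,1,0.9843,0.0004,4
aw,,2,0.9848,0.0003,4
aw,,3,0.9832,0.0003,4
aw,,4,0.9839,0.0006,4
aw,,5,0.9813,0.0004,4
aw,,6,0.9848,0.0005,4
aw,,7,0.9838,0.0011,4
aw,,8,0.9832,0.0004,4
aw,,9,0.9833,0.0004,4
aw,,10,0.9835,0.0010,4
aw,,11,0.9834,0.0004,4
crust_L,L*,1,67.2,0.662,5
crust_L,L*,2,65.8,0.861,5
crust_L,L*,3,66.4,1.151,5
crust_L,L*,4,67.2,0.481,5
crust_L,L*,5,69.8,0.762,5
crust_L,L*,6,66.2,1.201,5
crust_L,L*,7,66.6,0.921,5
crust_L,L*,8,66.5,0.992,5
crust_L,L*,9,65.5,1.372,5
crust_L,L*,10,68.5,0.561,5
crust_L,L*,11,69.0,0.731,5
crumb_L,L*,1,70.4,1.981,5
crumb_L,L*,2,71.4,2.27,5
crumb_L,L*,3,72.4,1.352,5
crumb_L,L*,4,71.2,1.172,5
crumb_L,L*,5,72.0,1.861,5
crumb_L,L*,6,69.5,2.371,5
crumb_L,L*,7,73.7,1.112,5
crumb_L,L*,8,70.8,2.623,5
crumb_L,L*,9,72.9,1.971,5
crumb_L,L*,10,74.8,1.472,5
crumb_L,L*,11,73.9,1.361,5
HARbr,g,1,3511,227,4
HARbr,g,2,2224,266,4
HARbr,g,3,2026,196,4
HARbr,g,4,3179,197,4
HARbr,g,5,3288,225,4
HARbr,g,6,2425,301,4
HARbr,g,7,3189,162,4
HARbr,g,8,1732,267,4
HARbr,g,9,1717,202,4
HARbr,g,10,3733,95,4
HARbr,g,11,3868,206.2,4
ADHbr,g.s,1,-40,14.5,4
ADHbr,g.s,2,-34,9.23,4
ADHbr,g.s,3,-22,7.98,4
ADHbr,g.s,4,-291,57.5,4
ADHbr,g.s,5,-389,86.1,4
ADHbr,g.s,6,-313,55.9,4
ADHbr,g.s,7,-204,98.2,4
ADHbr,g.s,8,-43,23.6,4
ADHbr,g.s,9,-91,38.1,4
ADHbr,g.s,10,-558,52.5,4
ADHbr,g.s,11,-496,90.10,4
COHbr,,1,0.432,0.008,4
COHbr,,2,0.422,0.024,4
COHbr,,3,0.430,0.023,4
COHbr,,4,0.454,0.009,4
COHbr,,5,0.453,0.009,4
COHbr,,6,0.445,0.012,4
COHbr,,7,0.438,0.014,4
COHbr,,8,0.425,0.015,4
COHbr,,9,0.434,0.021,4
COHbr,,10,0.440,0.007,4
COHbr,,11,0.426,0.012,4
RESbr,,1,0.171,0.005,4
RESbr,,2,0.170,0.005,4
RESbr,,3,0.175,0.006,4
RESbr,,4,0.177,0.006,4
RESbr,,5,0.172,0.005,4
RESbr,,6,0.173,0.005,4
RESbr,,7,0.167,0.006,4
RESbr,,8,0.155,0.020,4
RESbr,,9,0.147,0.013,4
RESbr,,10,0.166,0.004,4
RESbr,,11,0.161,0.004,4
MCA,mm2,1,1.73,0.23,24
MCA,mm2,2,4.10,0.88,24
MCA,mm2,3,3.49,0.77,24
MCA,mm2,4,1.52,0.18,24
MCA,mm2,5,1.14,0.17,24
MCA,mm2,6,2.81,0.67,24
MCA,mm2,7,1.76,0.26,24
MCA,mm2,8,5.00,2.04,24
MCA,mm2,9,4.57,1.34,24
MCA,mm2,10,1.30,0.17,24
MCA,mm2,11,1.36,0.18,24
CDE,cells/mm2,1,0.228,0.023,24
CDE,cells/mm2,2,0.125,0.022,24
CDE,cells/mm2,3,0.140,0.023,24
CDE,cells/mm2,4,0.245,0.018,24
CDE,cells/mm2,5,0.285,0.037,24
CDE,cells/mm2,6,0.162,0.028,24
CDE,cells/mm2,7,0.218,0.027,24
CDE,cells/mm2,8,0.108,0.026,24
CDE,cells/mm2,9,0.109,0.022,24
CDE,cells/mm2,10,0.263,0.029,24
CDE,cells/mm2,11,0.256,0.029,24
VFR,,1,0.350,0.015,24
VFR,,2,0.446,0.029,24
VFR,,3,0.427,0.025,24
VFR,,4,0.333,0.017,24
VFR,,5,0.288,0.011,24
VFR,,6,0.394,0.020,24
VFR,,7,0.341,0.012,24
VFR,,8,0.441,0.041,24
VFR,,9,0.426,0.028,24
VFR,,10,0.305,0.013,24
VFR,,11,0.310,0.011,24
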