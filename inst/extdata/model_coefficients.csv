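response,term,estimate
STIba,xanthan,43.1
STIba,guar,121.7
STIba,hpmc,16.7
STIba,xanthan:guar,-48.3
STIba,xanthan:hpmc,-12.1
STIba,guar:hpmc,-32.0
FIRba,xanthan,-502
FIRba,guar,-11241
FIRba,hpmc,713
FIRba,xanthan:guar,7354
FIRba,guar:hpmc,3087
SVO,xanthan,1.38
SVO,guar,-1.03
SVO,hpmc,0.59
SVO,xanthan:guar,0.44
SVO,guar:hpmc,0.49
BLO,xanthan,1.92
BLO,guar,37.1
BLO,hpmc,3.59
BLO,xanthan:guar,-14.8
BLO,guar:hpmc,-9.2
aw,xanthan,0.2439
aw,guar,0.2252
aw,hpmc,0.2463
aw,xanthan:guar,0.0048
aw,guar:hpmc,0.0053
crust_L,xanthan,18.9
crust_L,guar,-4.61
crust_L,hpmc,16.4
crust_L,xanthan:guar,13.1
crust_L,guar:hpmc,6.12
crumb_L,xanthan,29.9
crumb_L,guar,-56.1
crumb_L,hpmc,16.1
crumb_L,guar:hpmc,25.1
HARbr,xanthan,2311
HARbr,guar,-20773
HARbr,hpmc,580
HARbr,xanthan:guar,7799
HARbr,guar:hpmc,5825
ADHbr,xanthan,-795
ADHbr,guar,12163
ADHbr,hpmc,81
ADHbr,xanthan:guar,-3439
ADHbr,guar:hpmc,-3665
COHbr,xanthan,0.658
COHbr,guar,0.348
COHbr,hpmc,0.116
COHbr,xanthan:guar,-0.154
COHbr,xanthan:hpmc,-0.166
COHbr,guar:hpmc,-0.085
RESbr,xanthan,0.395
RESbr,guar,0.334
RESbr,hpmc,0.049
RESbr,xanthan:guar,-0.137
RESbr,xanthan:hpmc,-0.112
RESbr,guar:hpmc,-0.099
MCA,xanthan,-2.035
MCA,guar,3.154
MCA,hpmc,0.73
MCA,xanthan:guar,-3.866
CDE,xanthan,0.83
CDE,guar,-0.758
CDE,hpmc,0.042
CDE,xanthan:guar,0.259
CDE,xanthan:hpmc,-0.192
CDE,guar:hpmc,0.197
VFR,xanthan,-0.064
VFR,guar,1.089
VFR,hpmc,0.108
VFR,xanthan:guar,-0.412
VFR,guar:hpmc,-0.274
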