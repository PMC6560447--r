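quantity,value
xanthan,0.24
guar,0.60
hpmc,3.16
desirability,0.54
pred_SVO,2.57
pred_crust_L,67.0
pred_HARbr,2082
pred_CDE,0.142
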