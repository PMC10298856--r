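model,a,b,c,R2
PRM-VT,3.414,-0.021981,3.5557e-05,0.954
PRSV-VT,1.355,-0.0089,1.4854e-05,0.964
SAFT,0.593,-0.0040773,6.9106e-06,0.976
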