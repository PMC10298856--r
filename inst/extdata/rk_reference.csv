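T_K,property,A0,A1,A2,A3,s
288.15,HE,2063,-617,136,NA,6.3
298.15,HE,2380,-768,75,NA,6.6
308.15,HE,2667,-981,197,NA,7.8
318.15,HE,2978,-1107,204,NA,7
288.15,VE,-2.017,-0.227,-0.77,-0.25,0.007
298.15,VE,-1.979,-0.247,-0.765,-0.3,0.006
308.15,VE,-1.912,-0.306,-0.737,-0.31,0.006
318.15,VE,-1.847,-0.378,-0.642,-0.3,0.007
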