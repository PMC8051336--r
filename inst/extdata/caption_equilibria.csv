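source,t,C,D,x_min,x_mdl,x_max,x_current
Fig3B,32000,30.0820,3.5,0.3098,3.72,26.045,0.3096
Fig3C,33100,30.0834,2.1261,0.661,1.64,27.78,0.6478
Fig3D,33140,30.1132,1.4357,,,28.6,9.01
Fig3E,33141,28.5246,3.6068,0.3,3.93,24.3,24.72
Fig3F,33141.5,27.6767,6.5723,0.15,10.5,17.04,19.3307
Fig3G,33142.1,27.46,7.59,0.13,,,18.6191
Fig3H,33143.0,27.5,5.43,0.19,7.23,20.1,6.561
Fig3I,33143.2,27.51,5.06,0.2,6.46,20.84,6.47
Fig4B,33500,24.89,6.26,0.16,12.23,12.49,12.47
Fig4C,37850,27.22,5.35,0.19,7.1,19.92,7.67
Fig4D,42000,40.38,10.12,0.1,20.43,20.43,20.28
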