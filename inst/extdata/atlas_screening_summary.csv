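predictor,category,roc,pi,n_selected
AnnTMean,climate,0.66,7.6,26
DiuTRange,climate,0.58,8.1,23
Isotherm,climate,0.58,7.7,21
TSeason,climate,0.58,9.9,23
Tmax,climate,0.61,3.0,18
TWetQuar,climate,0.66,1.8,18
TDryQuar,climate,0.55,2.6,20
AnnPMean,climate,0.65,6.1,29
PSeason,climate,0.56,3.6,19
AltMean,topography,0.66,17.8,27
CumLenkm,hydromorphology,0.65,3.9,24
Strahler,hydromorphology,0.64,12.9,36
RtypMost,hydromorphology,0.61,11.3,32
Lusemax,anthropogenic,0.55,1.7,26
Popmean,anthropogenic,0.57,2.0,24
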