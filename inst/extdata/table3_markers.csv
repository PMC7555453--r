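label,formula,annotated_mz,delta_ppm,marker_species
C 50:3,C53H100NO6,846.7535,1.259,chicken
C 50:2,C53H102NO6,848.7682,1.339,chicken;pork
C 50:1,C53H104NO6,850.7836,1.559,chicken;pork
C 50:0,C53H106NO6,852.7975,4.820,chicken;pork
C 52:4,C55H102NO6,872.7683,2.104,chicken
C 52:3,C55H104NO6,874.7837,1.562,chicken
C 52:2,C55H106NO6,876.7995,1.672,pork;beef
C 52:1,C55H108NO6,878.8130,2.522,pork;beef
C 52:0,C55H110NO6,880.8246,4.112,pork;beef
C 54:6,C57H102NO6,896.7689,1.412,chicken
C 54:5,C57H104NO6,898.7841,1.898,chicken
C 54:4,C57H106NO6,900.7996,2.050,chicken
C 54:3,C57H108NO6,902.8148,3.636,pork;beef
C 54:2,C57H110NO6,904.8306,1.709,beef
C 54:1,C57H112NO6,906.8457,2.974,beef
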