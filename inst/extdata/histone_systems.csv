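pdbApo,resApo,pdbHolo,resHolo,targetName,sequence,kdMicromolar,rmsdStart
1xwh,NMR,2ke1,NMR,AIRE PHD finger,ARTKQTARKS,6.5,8.56
2fui,NMR,2fuu,NMR,BPTF PHD finger,ARTKQTARKSTGGKA,2.7,17.75
2gnq,1.8,2co0,2.25,WDR5,ARTKQTARKSTGGKA,3.3,8.21
2mny,NMR,2mnz,NMR,KDM5B PHD1 finger,ARTKQTARKS,6.4,18.33
2pv0,3.3,2pvc,3.69,DNMT3L,ARTKQTA,2.1,9.51
3o33,2.0,3o37,2.0,TRIM24 PHD-Bromo complex,ARTKQTARKS,8.6,27.18
3qln,1.90,3qlc,2.5,ARTX ADD,ARTKQTARKSTGGKA,3.7,13.28
3sox,2.65,3sou,1.8,UHRF1 PHD finger,ARTKQTARK,2.1,10.32
4ljn,3.0,4lk9,1.6,MOZ double PHD finger,ARTKQTARKSTGGKAPRKQLA,NA,15.02
4qf2,1.7,4q6f,1.91,BAZ2A PHD Zinc finger,ARTKQ,2.51,9.99
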