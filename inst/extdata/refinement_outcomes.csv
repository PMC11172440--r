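system,protocol,condition,rmsdStart,rmsdBest,deltaRmsd
3o33,P4,hydrated,27.18,4.41,NA
3o33,P4,no_hydration,27.18,15.77,NA
3qln,P4,hydrated,13.28,3.68,NA
4qf2,P4,holo_start,3.8,NA,1.53
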