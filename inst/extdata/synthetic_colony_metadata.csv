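breeding_ground,transect,sampling_point,x,y,id,life_stage,sex,hatch_day
ground1,T2,T2P1,497.962409702748,-1.81977758586209,bird001,adult,F,93
ground2,T4,T4P1,5002.04029547291,-0.596214682810573,bird002,adult,M,75
ground1,T3,T3P1,997.625310880262,0.999141639926017,bird003,adult,F,75
ground1,T1,T1P2,1.47729459576245,26.1880632872964,bird004,adult,M,110
ground2,T4,T4P3,4999.46675909482,57.721253671701,bird005,adult,M,75
ground1,T1,T1P1,-0.792260370906799,4.62086788107212,bird006,adult,M,90
ground1,T1,T1P4,0.65107016920301,86.2570037288698,bird007,adult,M,102
ground1,T2,T2P3,502.47227816213,60.6500858764158,bird008,adult,F,108
ground1,T2,T2P4,502.460118216347,86.6141220999097,bird009,adult,M,89
ground1,T1,T1P3,-0.0239564121445541,56.634396575881,bird010,adult,F,75
ground2,T4,T4P2,5000.98327607671,30.9355004730012,bird011,adult,M,111
ground1,T2,T2P2,498.066228991893,29.8003243110265,bird012,adult,F,94
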