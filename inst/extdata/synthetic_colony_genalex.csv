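4,12,2,9,3,,,,,
synthetic 12-bird example colony,,,ground1,ground2,,,,,
Sample,Pop,L01,,L02,,L03,,L04,
bird001,ground1,3,3,1,5,3,3,5,7
bird002,ground2,3,3,3,3,5,5,5,7
bird003,ground1,3,4,3,5,3,3,2,5
bird004,ground1,3,3,4,5,3,3,4,7
bird005,ground2,3,4,3,4,3,3,4,5
bird006,ground1,3,3,3,4,3,3,2,5
bird007,ground1,2,3,5,5,3,3,0,0
bird008,ground1,2,3,3,5,3,3,4,5
bird009,ground1,3,3,4,5,3,3,2,7
bird010,ground1,2,2,3,5,0,0,2,5
bird011,ground2,3,3,1,5,3,3,4,5
bird012,ground1,2,4,3,5,3,3,2,5
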