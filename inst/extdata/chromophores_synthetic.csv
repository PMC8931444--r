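"wavelength","HbO2","Hb","fat","water"
700,0.250883,2.176145,0.1003,0.020333
710,0.286611,2.058301,0.117403,0.020684
720,0.325494,2.01351,0.141667,0.021318
730,0.367471,2.049629,0.17098,0.022387
740,0.412415,2.132306,0.200111,0.02406
750,0.460124,2.180985,0.221894,0.026488
760,0.510325,2.114527,0.23,0.02974
770,0.562663,1.914934,0.221894,0.033736
780,0.616708,1.642015,0.200111,0.038198
790,0.671958,1.382096,0.17098,0.042653
800,0.727837,1.187755,0.141667,0.046499
810,0.783712,1.06251,0.117403,0.049148
820,0.838898,0.984182,0.1003,0.050192
830,0.892672,0.930453,0.089859,0.049567
840,0.944289,0.888324,0.084288,0.047651
850,0.992997,0.8523,0.081713,0.045297
860,1.038057,0.820434,0.081048,0.043809
870,1.07876,0.791985,0.08366,0.044898
880,1.114446,0.766537,0.099049,0.050595
890,1.144519,0.743765,0.156205,0.063091
900,1.168469,0.723389,0.30442,0.084408
910,1.185883,0.705155,0.565467,0.115855
920,1.196455,0.688839,0.851297,0.157313
930,1.2,0.674239,0.98,0.206567
940,1.196455,0.661174,0.851297,0.259013
950,1.185883,0.649482,0.565467,0.308055
960,1.168469,0.639021,0.304417,0.346301
970,1.144519,0.629659,0.156192,0.367303
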