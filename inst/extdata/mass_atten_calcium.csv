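energy_keV,mass_atten_cm2_g
1,8900
1.5,2730
2,1151
3,341
4,144
5,747
6,432
8,178
10,93.4
15,28.9
20,12.3
30,4.08
40,1.830
50,1.019
60,0.6578
80,0.3656
100,0.2451
150,0.1582
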