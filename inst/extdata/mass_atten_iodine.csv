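energy_keV,mass_atten_cm2_g
1,9000
2,1800
3,652
4,310
5,692
6,435
8,230
10,170
15,55
20,25
25,13.9
30,8.561
33.1999,6.55
33.2001,36.3
40,22.10
50,12.32
60,7.579
80,3.510
100,1.942
150,0.6573
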