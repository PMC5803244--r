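# NIST PSTAR reference values for protons in liquid water (I = 75 eV):
# total mass stopping power (MeV cm^2/g) and CSDA range (g/cm^2).
energy	stopping_power	csda_range
5	79.11	0.0362
10	45.67	0.1230
15	33.12	0.2539
20	26.07	0.4260
25	21.75	0.6370
30	18.76	0.8853
40	14.88	1.489
50	12.45	2.227
70	9.559	4.080
80	8.625	5.184
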