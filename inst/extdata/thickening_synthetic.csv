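# synthetic 90-min thickening test (generated by gen_thickening_curve,
#   a = 6.493 g/L, b = 0.0465, 1% lognormal noise, seed 2015)
time_min,conc_g_L
1,6.39343
1.26723,6.5303
1.60587,6.56585
2.035,6.71109
2.57881,6.81186
3.26794,6.89719
4.14123,6.81022
5.24788,7.05911
6.65026,7.04687
8.4274,7.23373
10.6794,7.28534
13.5333,7.27056
17.1498,7.45766
21.7327,7.57853
27.5403,7.58001
34.8998,7.71154
44.226,7.72241
56.0445,7.84443
71.0211,7.82072
90,7.89806
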