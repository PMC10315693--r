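# Electron collision (ionisation) mass stopping power for liquid water,
# MeV cm^2/g, as tabulated in the standard NIST ESTAR compilation.
# Radiative losses are intentionally excluded (soft-tissue radiative
# fraction < 1% below ~1 MeV); other tissues are obtained by density scaling.
# table_version: 1
energy_mev,stopping_power
0.010,22.56
0.015,16.47
0.020,13.17
0.030,9.653
0.040,7.777
0.050,6.603
0.060,5.797
0.080,4.757
0.100,4.115
0.150,3.238
0.200,2.793
0.300,2.355
0.400,2.148
0.500,2.034
0.600,1.963
0.800,1.886
1.000,1.849
1.250,1.829
1.500,1.822
2.000,1.824
2.500,1.834
3.000,1.846
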