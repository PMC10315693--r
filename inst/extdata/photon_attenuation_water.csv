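# Photon mass attenuation coefficients for liquid water, cm^2/g.
# mu_incoherent computed from the Klein-Nishina total cross-section
# (free-electron approximation, Z/A = 0.55509); mu_photoelectric from a
# E^-3 power law anchored at the standard 10 keV water value 4.944 cm^2/g.
# Coherent (Rayleigh) scattering intentionally excluded from transport.
# table_version: 1
energy_mev,mu_photoelectric,mu_incoherent
0.0100,4.944000e+00,2.140984e-01
0.0150,1.464889e+00,2.102515e-01
0.0200,6.180000e-01,2.065826e-01
0.0300,1.831111e-01,1.997321e-01
0.0400,7.725000e-02,1.934624e-01
0.0500,3.955200e-02,1.877023e-01
0.0600,2.288889e-02,1.823915e-01
0.0800,9.656250e-03,1.729198e-01
0.1000,4.944000e-03,1.647175e-01
0.1500,1.464889e-03,1.482898e-01
0.2000,6.180000e-04,1.358802e-01
0.3000,1.831111e-04,1.181524e-01
0.4000,7.725000e-05,1.058606e-01
0.5110,3.705235e-05,9.578537e-02
0.6000,2.288889e-05,8.941981e-02
0.8000,9.656250e-06,7.854308e-02
1.0000,4.944000e-06,7.060323e-02
1.2500,2.531328e-06,6.311914e-02
1.5000,1.464889e-06,5.735506e-02
2.0000,6.180000e-07,4.892534e-02
2.5000,3.164160e-07,4.296370e-02
3.0000,1.831111e-07,3.847306e-02
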