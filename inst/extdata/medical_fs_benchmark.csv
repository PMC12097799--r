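dataset,rbmo_mean,rbmo_sd,irbmo_mean,irbmo_sd
BCC,0.209143,0.014925,0.158678,0.005427
BCWD,0.013285,0.003015,0.009162,0.003342
BCWP,0.12178,0.001652,0.021917,0.001473
Cleveland,0.327749,0.002705,0.294999,0.015028
Dermatology,0.090265,0.004511,0.006225,0.002506
DRD,0.281317,0.005649,0.249178,0.009163
Hepatitis,0.08957,0.000865,0.000614,0.00048
ILPD,0.301455,0.001829,0.207832,0.010163
Lymphography,0.16949,0.01531,0.095993,0.017242
Parkinsons,0.028418,0.001634,0.019592,0.009075
PDC,0.113844,0.009212,0.071582,0.006723
Spectfheart,0.109387,0.017265,0.073164,0.014714
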