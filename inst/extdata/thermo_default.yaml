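# Standard transformed thermodynamic data at pH 7, 25 degC, 1 M / 1 atm.
# Formation energies (kJ/mol) from the classical anaerobe compilation of
# Thauer, Jungermann & Decker (1977, Bacteriol Rev 41:100-180).
# Midpoint potentials (mV): standard redox-couple values; the ferredoxin
# pool of acetogens is taken at -450 mV.
provenance: >
  delta_Gf values: Thauer, Jungermann & Decker (1977); E0' values: standard
  biochemical redox couples, ferredoxin at -450 mV.
delta_gf_prime:
  co: -137.2
  co2: -394.4
  h2: 0.0
  h2o: -237.2
  h: 0.0
  acetate: -369.4
  ethanol: -181.8
  butanediol: -322.0
  formate: -351.0
couples:
  co2_co: -520
  h_h2: -414
  fd: -450
  nad: -320
  nadp: -320
constants:
  faraday_kj_per_v: 96.485
  rt_kj: 2.47897
  ph: 7
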