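[
  {"treatment": "0.70kW-20", "power_kW": 0.70, "imc_db": 0.20,
   "g0": 2.100, "g1": -0.111, "g2": 2.81e-04, "g3": -1.37e-03,
   "g4": 1.00e-03, "g5": 2.966, "g6": -1.670, "g7": 0.0461},
  {"treatment": "0.70kW-35", "power_kW": 0.70, "imc_db": 0.35,
   "g0": 2.100, "g1": -0.100, "g2": 4.62e-04, "g3": -1.00e-02,
   "g4": 9.34e-04, "g5": 2.964, "g6": -1.674, "g7": 0.0329},
  {"treatment": "0.70kW-50", "power_kW": 0.70, "imc_db": 0.50,
   "g0": 2.119, "g1": -0.040, "g2": 5.07e-05, "g3": -1.99e-02,
   "g4": 4.58e-04, "g5": 2.853, "g6": -1.709, "g7": 0.0300},
  {"treatment": "0.35kW-20", "power_kW": 0.35, "imc_db": 0.20,
   "g0": 2.100, "g1": -0.151, "g2": 1.01e-04, "g3": -1.00e-02,
   "g4": 1.00e-05, "g5": 2.686, "g6": -1.264, "g7": 0.0700},
  {"treatment": "0.35kW-35", "power_kW": 0.35, "imc_db": 0.35,
   "g0": 2.160, "g1": -0.112, "g2": 5.00e-05, "g3": -1.00e-04,
   "g4": 5.93e-05, "g5": 2.820, "g6": -1.476, "g7": 0.0580},
  {"treatment": "0.35kW-50", "power_kW": 0.35, "imc_db": 0.50,
   "g0": 2.161, "g1": -0.100, "g2": 6.02e-05, "g3": -1.00e-02,
   "g4": 5.88e-04, "g5": 2.964, "g6": -1.602, "g7": 0.0506}
]
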