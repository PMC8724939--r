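[
  {"treatment": "0.70kW-20", "power_kW": 0.70, "imc_db": 0.20,
   "D0": 3.56e-03, "Ea": 30.315, "a0": 1.00e-06, "a1": 0.397},
  {"treatment": "0.70kW-35", "power_kW": 0.70, "imc_db": 0.35,
   "D0": 3.46e-03, "Ea": 30.314, "a0": 1.00e-06, "a1": 0.397},
  {"treatment": "0.70kW-50", "power_kW": 0.70, "imc_db": 0.50,
   "D0": 2.36e-03, "Ea": 29.026, "a0": 1.00e-06, "a1": 0.500},
  {"treatment": "0.35kW-20", "power_kW": 0.35, "imc_db": 0.20,
   "D0": 1.32e-03, "Ea": 29.000, "a0": 1.00e-03, "a1": 0.300},
  {"treatment": "0.35kW-35", "power_kW": 0.35, "imc_db": 0.35,
   "D0": 2.45e-03, "Ea": 30.300, "a0": 1.00e-03, "a1": 0.300},
  {"treatment": "0.35kW-50", "power_kW": 0.35, "imc_db": 0.50,
   "D0": 1.48e-03, "Ea": 29.011, "a0": 1.00e-03, "a1": 0.300}
]
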