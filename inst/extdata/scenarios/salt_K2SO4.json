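{
  "flux": {
    "J_water": 0.05,
    "C_cup": 6.25e-4,
    "FW": 31,
    "D": 8.9e-6,
    "h": 0.2,
    "uptake_rate": 0,
    "cup_volume": 0.25
  },
  "humidity": {
    "salt": "K2SO4",
    "phi_in": 5,
    "k_salt": 2,
    "k_leak": 0.05,
    "rh_ambient": 50,
    "chamber_volume": 20,
    "temperature": 20
  }
}
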