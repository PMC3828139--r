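{
  "label": "DN",
  "alpha": 1.4,
  "beta": 0.074,
  "gamma": 0.22,
  "tau_r": 66,
  "n_y": 3.7,
  "tau_y": 18,
  "n_z": 7.8,
  "tau_z": 13,
  "units": {
    "alpha": "mV*um^2*ms/photon",
    "beta": "(photons/um^2/ms)^-1",
    "tau_r": "ms",
    "tau_y": "ms",
    "tau_z": "ms"
  }
}
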