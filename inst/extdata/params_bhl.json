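{
  "label": "BHL",
  "alpha": 1.1,
  "beta": 0.044,
  "gamma": 0.93,
  "tau_r": 39,
  "n_y": 1.5,
  "tau_y": 38,
  "n_z": 7,
  "tau_z": 20,
  "units": {
    "alpha": "mV*um^2*ms/photon",
    "beta": "(photons/um^2/ms)^-1",
    "tau_r": "ms",
    "tau_y": "ms",
    "tau_z": "ms"
  }
}
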