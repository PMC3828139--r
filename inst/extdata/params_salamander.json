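{
  "label": "Salamander Fit",
  "alpha": 2.0,
  "beta": 0.16,
  "gamma": 0.23,
  "tau_r": 28,
  "n_y": 4,
  "tau_y": 33,
  "n_z": 10,
  "tau_z": 19,
  "units": {
    "alpha": "mV*um^2*ms/photon",
    "beta": "(photons/um^2/ms)^-1",
    "tau_r": "ms",
    "tau_y": "ms",
    "tau_z": "ms"
  },
  "note": "Published gain is in arbitrary units; alpha here defaults to the typical single-photon value of 2 mV um^2 ms/photon."
}
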