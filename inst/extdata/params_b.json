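{
  "label": "B",
  "alpha": 2.1,
  "beta": 0.067,
  "gamma": 0.57,
  "tau_r": 50,
  "n_y": 3,
  "tau_y": 20,
  "n_z": 7,
  "tau_z": 20,
  "units": {
    "alpha": "mV*um^2*ms/photon",
    "beta": "(photons/um^2/ms)^-1",
    "tau_r": "ms",
    "tau_y": "ms",
    "tau_z": "ms"
  },
  "note": "Kernel shapes, time constants, tau_r and alpha were set to typical values rather than fitted in the source."
}
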