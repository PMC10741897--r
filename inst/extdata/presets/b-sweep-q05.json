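{
  "name": "b-sweep-q05",
  "description": "Radiation-parameter sweep at order q = 0.5; b in (-1.3, 1.3)",
  "params": { "a": 0.78, "b": 0.1, "k": 0.1, "p": 0.3, "g": 0.8 },
  "order": 0.5,
  "h": 0.001,
  "M": 3,
  "initial": [1, 1, -1, 0, 0],
  "b_sweep": [-1.3, 1.3]
}
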