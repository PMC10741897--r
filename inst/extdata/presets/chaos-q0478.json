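{
  "name": "chaos-q0478",
  "description": "Chaotic reference regime of the memristive Hopfield network",
  "params": { "a": 0.78, "b": 0.1, "k": 0.1, "p": 0.3, "g": 0.8 },
  "order": 0.478,
  "h": 0.001,
  "M": 3,
  "initial": [1, 1, -1, 0, 0]
}
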