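{
  "name": "multiscroll",
  "description": "Direction-controllable multi-scroll regime; sweep b over +/-(0.9, 1.6)",
  "params": { "a": 0.78, "b": 1.2, "k": 0.1, "p": 2.6, "g": 2.5 },
  "order": 0.478,
  "h": 0.001,
  "M": 3,
  "initial": [1, 1, -1, 0, 0],
  "b_sweep": [0.9, 1.6]
}
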