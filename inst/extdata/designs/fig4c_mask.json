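{
  "base": "J4-I",
  "mask": {
    "cut_edges": ["e_r0c2_E", "e_r1c2_E", "e_r2c2_E", "e_r3c2_E", "e_r4c2_E", "e_r5c2_E"]
  },
  "target_shape": [
    [0, 0],
    [1, 0],
    [2, 0],
    [3, 0],
    [4, 0],
    [5, 0],
    [0, 1],
    [1, 1],
    [2, 1],
    [3, 1],
    [4, 1],
    [5, 1],
    [0, 2],
    [1, 2],
    [2, 2],
    [3, 2],
    [4, 2],
    [5, 2]
  ]
}
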