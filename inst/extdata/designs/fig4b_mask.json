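{
  "base": "J4-I",
  "mask": {
    "cut_edges": ["e_r0c1_E", "e_r1c1_E", "e_r2c1_E", "e_r3c1_E", "e_r4c1_E", "e_r5c1_E", "e_r0c3_E", "e_r1c3_E", "e_r2c3_E", "e_r3c3_E", "e_r4c3_E", "e_r5c3_E"]
  },
  "target_shape": [
    [0, 2],
    [1, 2],
    [2, 2],
    [3, 2],
    [4, 2],
    [5, 2],
    [0, 3],
    [1, 3],
    [2, 3],
    [3, 3],
    [4, 3],
    [5, 3]
  ]
}
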