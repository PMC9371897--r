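{
  "base": "J4-I",
  "mask": {
    "cut_edges": ["e_r1c0_S", "e_r1c1_S", "e_r1c2_S", "e_r1c3_S", "e_r1c4_S", "e_r1c5_S", "e_r3c0_S", "e_r3c1_S", "e_r3c2_S", "e_r3c3_S", "e_r3c4_S", "e_r3c5_S"]
  },
  "target_shape": [
    [2, 0],
    [3, 0],
    [2, 1],
    [3, 1],
    [2, 2],
    [3, 2],
    [2, 3],
    [3, 3],
    [2, 4],
    [3, 4],
    [2, 5],
    [3, 5]
  ]
}
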