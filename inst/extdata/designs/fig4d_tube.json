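{
  "motif_type": "J4",
  "rows": 6,
  "cols": 6,
  "connectivity": "square_grid",
  "domains": {
    "root": 11,
    "stem": 10
  },
  "boundary": {
    "policy": "overhang",
    "sides": ["E", "W"],
    "length": 3,
    "complementary": true
  },
  "internal_nicks_per_motif": 0,
  "mask": "all",
  "name": "fig4d_tube"
}
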