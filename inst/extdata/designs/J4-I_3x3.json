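{
  "motif_type": "J4",
  "rows": 3,
  "cols": 3,
  "connectivity": "square_grid",
  "domains": {
    "root": 11,
    "stem": 10
  },
  "boundary": {
    "policy": "blunt"
  },
  "internal_nicks_per_motif": 0,
  "mask": "all",
  "name": "J4-I_3x3"
}
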