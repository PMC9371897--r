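{
  "motif_type": "J4",
  "rows": 6,
  "cols": 6,
  "connectivity": "square_grid",
  "domains": {
    "root": 13,
    "stem": 6
  },
  "boundary": {
    "policy": "blunt"
  },
  "internal_nicks_per_motif": 0,
  "mask": "all",
  "name": "J4-II"
}
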