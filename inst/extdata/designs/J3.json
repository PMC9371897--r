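{
  "motif_type": "J3",
  "rows": 6,
  "cols": 7,
  "connectivity": "brick_wall",
  "domains": {
    "root": 11,
    "stem": 10
  },
  "boundary": {
    "policy": "blunt"
  },
  "internal_nicks_per_motif": 0,
  "mask": "all",
  "name": "J3"
}
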