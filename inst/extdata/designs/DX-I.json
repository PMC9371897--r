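{
  "motif_type": "DX",
  "rows": 6,
  "cols": 6,
  "connectivity": "dx_rows",
  "domains": {
    "rigidity": 21,
    "sticky": 10
  },
  "boundary": {
    "policy": "blunt"
  },
  "internal_nicks_per_motif": 1,
  "mask": "all",
  "name": "DX-I"
}
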