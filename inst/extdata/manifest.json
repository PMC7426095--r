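{
  "n_species": 185,
  "n_reactions": 207,
  "fingerprint": "56652dbedb95abea3bc518edcd6d9f95"
}
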