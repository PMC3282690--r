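name: 4-state
K: 4
edges:
- - 1
  - 2
- - 2
  - 3
- - 3
  - 4
- - 2
  - 1
- - 3
  - 2
- - 4
  - 3
detailed_balance: no
channels:
- family: poisson
  tie_groups:
  - 1
  - 2
  - 3
  - 4
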