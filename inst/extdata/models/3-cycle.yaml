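name: 3-cycle
K: 3
edges:
- - 2
  - 1
- - 3
  - 1
- - 1
  - 2
- - 3
  - 2
- - 1
  - 3
- - 2
  - 3
detailed_balance: no
channels:
- family: poisson
  tie_groups:
  - 1
  - 2
  - 3
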