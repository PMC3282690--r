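name: 1-state
K: 1
edges: []
detailed_balance: no
channels:
- family: poisson
  tie_groups: 1
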