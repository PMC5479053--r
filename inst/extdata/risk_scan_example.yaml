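study: risk_scan
hill: 2
designs:
  - kind: knock_in
  - kind: pre_post
    epsilon: 0.5
  - kind: bac
alpha:
  from: 0.005
  to: 0.12
  n: 12
gamma:
  from: 0.05
  to: 1.0
  n: 12
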