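# Default MEWS point bands. Each vital maps to [lower, upper, points]
# triples (upper exclusive; ~ means unbounded); avpu maps consciousness
# levels to points. Loadable with read_score_table().
sbp:
- [~, 71, 3]
- [71, 81, 2]
- [81, 101, 1]
- [101, 200, 0]
- [200, ~, 2]
pulse:
- [~, 40, 2]
- [40, 51, 1]
- [51, 101, 0]
- [101, 111, 1]
- [111, 130, 2]
- [130, ~, 3]
resp:
- [~, 9, 2]
- [9, 15, 0]
- [15, 21, 1]
- [21, 30, 2]
- [30, ~, 3]
temp:
- [~, 35, 2]
- [35, 38.5, 0]
- [38.5, ~, 2]
avpu:
  alert: 0
  voice: 1
  pain: 2
  unresponsive: 3
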