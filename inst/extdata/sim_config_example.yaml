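# Example simulation config: two disjoint planted templates over a small
# background namespace. All probabilities are per-case.
n_cases: 200
seed: 7
templates:
  - herbs: [Gan-cao, Huang-qi, Dang-gui]
    weight: 0.5
    inclusion_prob: 0.9
  - herbs: [Mai-dong, Wu-wei-zi]
    weight: 0.3
    inclusion_prob: 0.9
background_probs:
  San-qi: 0.4
  Yan-hu-suo: 0.3
  Chuan-xiong: 0.2
syndrome_rules:
  "1":
    tags: [qi deficiency, blood stasis]
    prob: 0.9
  "0":
    tags: [qi deficiency]
    prob: 0.2
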