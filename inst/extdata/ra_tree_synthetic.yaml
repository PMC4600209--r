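# SYNTHETIC decision tree for the Contact Assessment rehabilitation
# algorithm. Assembled from the algorithm's published ingredients (ADL
# decline D5 at the root, stair climbing D4D, IADL difficulty D4A, the
# Self-Reliance indicator over C1/C2A-C2D). This is NOT the licensed
# algorithm: the exact split sequence, thresholds and leaf assignments of
# the real tree are published only in the instrument manual.
test: {item: D5, op: ge, value: 1}
"yes":
  test: {predicate: self_reliance}
  "yes": {score: 5}
  "no": {score: 4}
"no":
  test: {item: D4D, op: ge, value: 1}
  "yes": {score: 3}
  "no":
    test: {item: D4A, op: ge, value: 1}
    "yes": {score: 2}
    "no": {score: 1}
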