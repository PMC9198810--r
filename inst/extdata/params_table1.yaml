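# Baseline SEWIR rate constants (per day; Lambda in individuals/day).
# The two control variables m (vaccination success rate) and k1
# (government control rate) are scenario-level and deliberately absent.
Lambda: 15.0
beta: 0.5
mu: 0.08
epsilon: 0.8
gamma: 0.06
vartheta: 0.8
k2: 0.01
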