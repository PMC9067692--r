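# reduced-scale cooperation-surface sweep
mode: sweep
scenarios: [voluntary, compulsory]
n: [20, 60, 120]
omega: [0.80, 0.925, 1.05]
replicates: 10
periods: 2000
burn_in: 1000
seed: 1
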