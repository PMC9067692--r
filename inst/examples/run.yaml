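# one voluntary-scenario run
scenario: voluntary
n: 60
omega: 0.925
periods: 2000
burn_in: 1000
seed: 1
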