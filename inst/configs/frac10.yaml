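# Sensitivity analysis: same 40-scenario grid with a 10% validation sample.
r2: [0.2, 0.4, 0.6, 0.8, 0.9]
skewness: [0.1, 1, 1.5, 3]
linear: [true, false]
differential: false
val_fraction: 0.1
n: 650
n_reps: 5000
seed: 2021
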