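# Differential measurement error: WC | VAT ~ N(0.8 VAT + tau U, tau^2) and
# the outcome gains a sqrt(0.3) U term, U ~ Bernoulli(0.5). tau is fixed at
# 0.44 (the value corresponding to R^2 = 0.8 under the linear model) and the
# residual skewness is 0.1.
r2: 0.8
skewness: 0.1
linear: true
differential: true
tau: 0.44
val_fraction: 0.4
n: 650
n_reps: 5000
seed: 2021
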