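Synthetic fixtures (no experimental data).

- synthetic-exchange-curve.tsv — exchange correlation curve generated from
  the package's modified Eyring closed form (eps = 2.6e-2, k1 = 1.0e-8 1/s,
  k2 = 6.8e5 1/s, 0.5% additive Gaussian noise, seed 42) via
  micellex::synth_curves(); used by examples and the command-line `fit`
  subcommand.
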