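# Genetic-confound preset: kappa_a = 2, delta = 0; the within-pair effect
# should vanish in MZ pairs but persist (attenuated) in DZ pairs.
simulate:
  scenario: genetic
  effect: strong
ses: ses
targets: intercept
random: intercept
seed: 20260102
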