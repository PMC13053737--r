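# Shared-environment-confound preset: kappa_c = 2, delta = 0; the within-pair
# effect should vanish equally in MZ and DZ pairs.
simulate:
  scenario: shared_env
  effect: strong
ses: ses
targets: intercept
random: intercept
seed: 20260103
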