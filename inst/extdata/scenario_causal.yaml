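# Pure-causal preset: direct SES path only (delta = 2 T-units per SES SD).
# Regenerates identically via run_pipeline(config, out, seed = 20260101).
simulate:
  scenario: causal
  effect: strong
ses: ses
targets: intercept
random: intercept
seed: 20260101
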