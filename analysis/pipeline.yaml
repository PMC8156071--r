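# Shared configuration for the numbered analysis drivers.
# Desk-scale study conditions: three morphology classes rendered at
# 1 um/px, 15 patients per class with 12-24 extractable patches each,
# the base (phi = 0) family member, and the published 5 x 5 QC grid.
workdir: results/run
seed: 20260929
synth:
  cases_per_class: 15
  patches_per_case: [12, 24]
  um_per_px: 1.0
  classes: [SLL_CLL, DLBCL, LN_LUNG]
train:
  phi: 0
  candidate_lrs: [0.01, 0.003]
  screen_epochs: 4
  epochs: 16
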