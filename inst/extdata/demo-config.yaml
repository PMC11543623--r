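# Demo run: 20-subject arms, injected wake relative-delta and
# wake-to-wake transition effects for the 50 mg arm.
seed: 42
cohort:
  n_per_arm:
    placebo: 20
    "25": 20
    "50": 20
  n_sites: 4
effects:
- feature: wake_rel_delta
  arm: "50"
  month: 1
  delta: 4.04
- feature: wake_rel_delta
  arm: "50"
  month: 3
  delta: 4.33
transitions:
  enabled: yes
  n_epochs: 240
  deltas:
  - treatment: "50"
    month: 3
    from: W
    to: W
    delta: -0.069
  - treatment: "50"
    month: 3
    from: W
    to: N1
    delta: 0.069
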