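# Example scenario: the current-service baseline at desk scale.
# All unset keys fall back to the package defaults documented in
# ?scenario_config. Arrival means follow the reference case mix applied to
# 119 new attendances per month.
regimen: PRN
virtual_clinic: false
arrivals:
  AMD: 20.5
  DR: 50.3
  MR: 48.2
prevalent:
  n: 600
  eligible_frac: 0.21
horizon_months: 15
warmup_months: 3
report_months: 12
replications: 20
seed: 1
virtual_fu_cost: 37.5
booking:
  dna_prob: 0.05    # assumed: not published for the reference service
  cancel_prob: 0.03 # assumed
  rebook_within_days: 14
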