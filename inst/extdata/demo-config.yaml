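# Demonstration pipeline configuration: 2,000 families, 100 variants,
# pure fetal effect (child OR 0.8 per SD) at 17% prevalence.
seed: 42
simulate:
  n_snps: 100
  n_families: 2000
  n_children: 2
  maf_low: 0.05
  maf_high: 0.5
  h2_maternal: 0.02
  h2_fetal: 0.05
scenario:
  beta_mother: 0.0
  beta_child: -0.223
  prevalence: 0.17
  mediation: direct_pgs
score:
  scores: [M-SPECIFIC, F-SPECIFIC]
  standardize: whole_cohort
assoc:
  parent: mother
  score: M-SPECIFIC
  covariates: [child_age]
  filter: none
sibling:
  enabled: true
power:
  enabled: false
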