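# Normalized, intact-DNA cohort: every reaction receives 5 ng
# (2 ul of a 2.5 ng/ul dilution) of undegraded genomic DNA.
name: normalized_intact
seed: 101
n_replicates: 3
pcr_cycles: 26
cohort:
  n_samples: 400
  cn_distribution:
    "2": 1.0
  input:
    type: normalized
    ng: 5.0
  degradation:
    type: intact
noise:
  ct_noise_sd: 0.08
  area_noise_cv: 0.05
assays:
  qpcr_target:
    name: PRELID1_qpcr
    efficiency: 1.0823
    amplicon_length: 107
  qpcr_reference:
    name: RNaseP_qpcr
    efficiency: 1.1418
    amplicon_length: 87
  prt:
    name: PRELID1_prt
    efficiency: 0.95
    amplicon_length: 299
    paralog_length: 169
    reference_copies: 2
calling:
  modal_cn: 2
  reference_copies: 2
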