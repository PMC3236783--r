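# Non-normalized cohort: per-reaction input DNA varies lognormally
# (mean 13.28 ng, clamped to 2-120 ng); target and reference qPCR assays
# differ in efficiency by 5.95 percentage points, so delta-Ct -- and the
# called copy number -- drifts with input amount.
name: nonnormalized
seed: 102
n_replicates: 3
pcr_cycles: 26
cohort:
  n_samples: 400
  cn_distribution:
    "2": 1.0
  input:
    type: lognormal
    mean_ng: 13.28
    sdlog: 0.8
    min_ng: 2
    max_ng: 120
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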