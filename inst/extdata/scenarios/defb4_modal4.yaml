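# Multiallelic cluster scenario: modal copy number 4 with substantial
# spread (copy numbers 2-8), assayed in 366 normalized, intact samples by a
# 127 bp qPCR amplicon (7.36-point efficiency gap to the reference) and a
# 443 bp PRT amplicon.
name: defb4_modal4
seed: 104
n_replicates: 3
pcr_cycles: 30
cohort:
  n_samples: 366
  cn_distribution:
    "2": 0.03
    "3": 0.22
    "4": 0.38
    "5": 0.25
    "6": 0.08
    "7": 0.03
    "8": 0.01
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
    name: DEFB4_qpcr
    efficiency: 1.0
    amplicon_length: 127
  qpcr_reference:
    name: RNaseP_qpcr
    efficiency: 1.0736
    amplicon_length: 87
  prt:
    name: DEFB4_prt
    efficiency: 0.95
    amplicon_length: 443
    paralog_length: 443
    reference_copies: 2
calling:
  modal_cn: 4
  reference_copies: 2
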