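# Shared assay profiles and configs used across the suite.

prelid1_qpcr <- function(e = 1.0823) {
  assay_profile("PRELID1_qpcr", efficiency = e, amplicon_length = 107,
                role = "qpcr_target")
}

rnasep_qpcr <- function(e = 1.1418) {
  assay_profile("RNaseP_qpcr", efficiency = e, amplicon_length = 87,
                role = "qpcr_reference")
}

prelid1_prt <- function(e = 0.95) {
  assay_profile("PRELID1_prt", efficiency = e, amplicon_length = 299,
                role = "prt_pair", paralog_length = 169,
                reference_copies = 2)
}

# Noise-free, deterministic-template configuration for closed-form checks.
exact_config <- function(n = 3, cn = c("2" = 1), ...) {
  sim_config(n, cn, ct_noise_sd = 0, area_noise_cv = 0,
             template_poisson = FALSE, ...)
}

# A minimal cohort with chosen input masses and copy numbers.
toy_cohort <- function(input_mass, true_cn = 2, mean_fragment_length = Inf) {
  n <- max(length(input_mass), length(true_cn))
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    true_cn = rep_len(true_cn, n),
    input_mass = rep_len(input_mass, n),
    mean_fragment_length = mean_fragment_length,
    cohort_label = "toy"
  )
}
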