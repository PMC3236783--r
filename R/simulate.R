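#' Fraction of template molecules spanning an amplicon intact
#'
#' Under uniform random breakage of genomic DNA into fragments of mean
#' length `lambda`, the probability that a given `amplicon_length`-bp locus
#' lies entirely within one fragment is `exp(-amplicon_length / lambda)`.
#' This is why long amplicons lose template faster than short ones as DNA
#' degrades.
#'
#' @param amplicon_length Amplicon length in bp (> 0).
#' @param mean_fragment_length Mean fragment length `lambda` in bp (> 0, may
#'   be `Inf` for intact DNA).
#' @return Fraction in (0, 1]; decreasing in amplicon length, increasing in
#'   fragment length.
#' @examples
#' intact_fraction(107, Inf)   # 1: intact DNA
#' intact_fraction(299, 500)   # exp(-0.598)
#' @export
intact_fraction <- function(amplicon_length, mean_fragment_length) {
  if (any(amplicon_length <= 0) || any(mean_fragment_length <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  exp(-amplicon_length / mean_fragment_length)
}

# Expected amplifiable template molecules for one locus in one reaction.
# `copies_per_diploid` is the locus copy number per diploid genome; a
# diploid genome is two haploid genome equivalents.
template_molecules <- function(input_mass, copies_per_diploid,
                               amplicon_length, mean_fragment_length) {
  input_mass * GENOMES_PER_NG * (copies_per_diploid / 2) *
    intact_fraction(amplicon_length, mean_fragment_length)
}

# Realise the template count: Poisson-distributed molecules, or the
# expectation itself when stochastic template sampling is switched off.
draw_templates <- function(mean_n, poisson) {
  if (poisson) rpois(length(mean_n), mean_n) else mean_n
}

# Threshold cycle for n template molecules on an assay, before noise.
ct_from_templates <- function(n, assay, detection_threshold) {
  assay_intercept(assay, detection_threshold) -
    log10(n) / log10(1 + assay$efficiency)
}

#' Simulate a single threshold cycle
#'
#' The amplifiable template count is drawn (Poisson, or its expectation when
#' `config$template_poisson` is off) from the sample's DNA mass, its copy
#' number at the assayed locus, and the fraction of molecules left intact by
#' degradation. The Ct then follows the log-linear amplification model
#' `Ct = (log10(T) - log10(N)) / log10(1 + E)` plus Gaussian cycling noise.
#' Reactions with no amplifiable template, or whose Ct would exceed
#' `config$max_cycles`, are reported as missing (`NA`).
#'
#' @param sample One row of a [make_cohort()] tibble (or any list with
#'   `true_cn`, `input_mass`, `mean_fragment_length`).
#' @param assay An [assay_profile()] with role `qpcr_target` or
#'   `qpcr_reference`. A reference assay interrogates an invariant two-copy
#'   locus regardless of the sample's `true_cn`.
#' @param config A [sim_config()].
#' @return Ct in cycles, or `NA` for no amplification. Expected Ct drops by
#'   `1 / log10(1 + E)` cycles per tenfold increase in input.
#' @export
simulate_ct <- function(sample, assay, config) {
  stopifnot(inherits(assay, "assay_profile"), inherits(config, "sim_config"))
  if (!assay$role %in% c("qpcr_target", "qpcr_reference")) {
    stop("`assay` must have role qpcr_target or qpcr_reference",
         call. = FALSE)
  }
  copies <- if (assay$role == "qpcr_target") sample$true_cn else 2
  mean_n <- template_molecules(sample$input_mass, copies,
                               assay$amplicon_length,
                               sample$mean_fragment_length)
  n <- draw_templates(mean_n, config$template_poisson)
  if (n <= 0) return(NA_real_)
  ct <- ct_from_templates(n, assay, config$detection_threshold) +
    rnorm(1, 0, config$ct_noise_sd)
  if (ct > config$max_cycles) NA_real_ else ct
}

#' Simulate a qPCR plate for a cohort
#'
#' Runs every sample in `config$n_replicates` technical replicates of a
#' duplex target/reference qPCR. Both Cts of a replicate see the same
#' sample DNA mass but independent template-sampling and cycling noise.
#'
#' @param cohort A [make_cohort()] tibble.
#' @param target_assay [assay_profile()] with role `qpcr_target`.
#' @param reference_assay [assay_profile()] with role `qpcr_reference`.
#' @param config A [sim_config()]; results are reproducible under its seed.
#' @return A Ct table: tibble with columns `sample_id`, `replicate_index`,
#'   `ct_target`, `ct_reference`, `input_mass`; one row per sample x
#'   replicate, missing Cts as `NA`.
#' @export
simulate_qpcr_plate <- function(cohort, target_assay, reference_assay,
                                config) {
  stopifnot(inherits(config, "sim_config"))
  if (target_assay$role != "qpcr_target") {
    stop("`target_assay` must have role qpcr_target", call. = FALSE)
  }
  if (reference_assay$role != "qpcr_reference") {
    stop("`reference_assay` must have role qpcr_reference", call. = FALSE)
  }
  set.seed(config$seed)
  reps <- config$n_replicates
  idx <- rep(seq_len(nrow(cohort)), each = reps)

  one_channel <- function(assay, copies_per_diploid) {
    mean_n <- template_molecules(cohort$input_mass[idx],
                                 copies_per_diploid[idx],
                                 assay$amplicon_length,
                                 cohort$mean_fragment_length[idx])
    n <- draw_templates(mean_n, config$template_poisson)
    ct <- ifelse(n > 0,
                 ct_from_templates(pmax(n, .Machine$double.xmin), assay,
                                   config$detection_threshold) +
                   rnorm(length(n), 0, config$ct_noise_sd),
                 NA_real_)
    ifelse(!is.na(ct) & ct > config$max_cycles, NA_real_, ct)
  }

  tibble::tibble(
    sample_id = cohort$sample_id[idx],
    replicate_index = rep(seq_len(reps), times = nrow(cohort)),
    ct_target = one_channel(target_assay, cohort$true_cn),
    ct_reference = one_channel(reference_assay, rep(2, nrow(cohort))),
    input_mass = cohort$input_mass[idx]
  )
}

#' Simulate an end-point PRT run for a cohort
#'
#' A paralog ratio test amplifies the variable target locus and an
#' invariant-copy paralog with one primer pair, so both products share a
#' single amplification efficiency; copy number is read from the
#' target/paralog peak-area ratio. Peak areas are modelled at the
#' ratio-relevant level: area is proportional to the number of intact
#' template molecules times `(1 + E)^cycles`, with multiplicative
#' measurement noise. Template degradation acts on the full pre-digestion
#' product length for both loci, so it inflates the spread of the ratio
#' without biasing its expectation.
#'
#' @param cohort A [make_cohort()] tibble.
#' @param prt_assay [assay_profile()] with role `prt_pair`.
#' @param config A [sim_config()]; reproducible under its seed.
#' @return A peak table: tibble with columns `sample_id`,
#'   `replicate_index`, `area_target`, `area_paralog` (arbitrary
#'   fluorescence units, >= 0).
#' @export
simulate_prt_run <- function(cohort, prt_assay, config) {
  stopifnot(inherits(config, "sim_config"))
  if (prt_assay$role != "prt_pair") {
    stop("`prt_assay` must have role prt_pair", call. = FALSE)
  }
  # decouple the PRT random stream from the qPCR plate run at the same seed
  set.seed((config$seed + 1013904223L) %% .Machine$integer.max)
  reps <- config$n_replicates
  idx <- rep(seq_len(nrow(cohort)), each = reps)
  gain <- (1 + prt_assay$efficiency)^config$pcr_cycles

  one_locus <- function(copies_per_diploid) {
    mean_n <- template_molecules(cohort$input_mass[idx],
                                 copies_per_diploid[idx],
                                 prt_assay$amplicon_length,
                                 cohort$mean_fragment_length[idx])
    n <- draw_templates(mean_n, config$template_poisson)
    pmax(n * gain * (1 + rnorm(length(n), 0, config$area_noise_cv)), 0)
  }

  tibble::tibble(
    sample_id = cohort$sample_id[idx],
    replicate_index = rep(seq_len(reps), times = nrow(cohort)),
    area_target = one_locus(cohort$true_cn),
    area_paralog = one_locus(rep(prt_assay$reference_copies, nrow(cohort)))
  )
}
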