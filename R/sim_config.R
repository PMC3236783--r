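#' Input-DNA models for simulated cohorts
#'
#' `input_normalized()` gives every sample the same mass of DNA per reaction,
#' emulating a plate where concentrations were measured and adjusted before
#' assaying (the default 5 ng corresponds to 2 ul of a 2.5 ng/ul dilution).
#' `input_lognormal()` emulates a non-normalized cohort in which each sample
#' was resuspended without quantification, so per-reaction input varies over
#' more than an order of magnitude; draws are clamped to `[min_ng, max_ng]`.
#'
#' @param ng Fixed DNA mass per reaction, in ng.
#' @param mean_ng Arithmetic mean of the lognormal input distribution, ng.
#' @param sdlog Standard deviation of log input.
#' @param min_ng,max_ng Clamp bounds, ng (observed ranges of real
#'   non-normalized cohorts are finite; default 2-120 ng).
#' @return A list describing the input model, for use in [sim_config()].
#' @export
input_normalized <- function(ng = 5) {
  stopifnot(is.numeric(ng), ng > 0)
  list(type = "normalized", ng = ng)
}

#' @rdname input_normalized
#' @export
input_lognormal <- function(mean_ng = 13.28, sdlog = 0.8,
                            min_ng = 2, max_ng = 120) {
  stopifnot(mean_ng > 0, sdlog >= 0, min_ng > 0, max_ng > min_ng)
  list(type = "lognormal", mean_ng = mean_ng, sdlog = sdlog,
       min_ng = min_ng, max_ng = max_ng)
}

#' Simulation configuration
#'
#' Collects every knob of the assay simulator: cohort composition, input-DNA
#' model, template integrity, measurement noise and the seed from which all
#' randomness flows.
#'
#' @param n_samples Number of samples in the cohort.
#' @param cn_distribution Named numeric vector mapping integer copy numbers
#'   to probabilities, e.g. `c("1" = 0.1, "2" = 0.8, "3" = 0.1)`. Must sum
#'   to 1.
#' @param input_model See [input_normalized()] / [input_lognormal()].
#' @param mean_fragment_length Mean template fragment length in bp under a
#'   random-breakage degradation model; `Inf` (default) means intact genomic
#'   DNA.
#' @param ct_noise_sd Additive Gaussian noise on each Ct, in cycles.
#' @param area_noise_cv Multiplicative Gaussian noise on each peak area
#'   (coefficient of variation).
#' @param n_replicates Technical replicates per sample (default triplicate).
#' @param pcr_cycles End-point PCR cycles for the PRT arm (kept below
#'   plateau; default 26).
#' @param detection_threshold Molecule-equivalents at which the qPCR
#'   fluorescence threshold is crossed. Only Ct differences matter
#'   downstream, so this fixes an arbitrary absolute scale.
#' @param max_cycles Cycling limit; a reaction whose Ct would exceed it is
#'   reported as missing (no amplification call).
#' @param template_poisson Draw the number of amplifiable template molecules
#'   from a Poisson distribution (`TRUE`, realistic) or use its expectation
#'   (`FALSE`, for closed-form checks).
#' @param seed Integer seed; identical configurations with identical seeds
#'   reproduce simulated tables bit for bit.
#' @param cohort_label Free-text label stored on each sample.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples,
                       cn_distribution = c("2" = 1),
                       input_model = input_normalized(),
                       mean_fragment_length = Inf,
                       ct_noise_sd = 0.08,
                       area_noise_cv = 0.05,
                       n_replicates = 3,
                       pcr_cycles = 26,
                       detection_threshold = 1e10,
                       max_cycles = 40,
                       template_poisson = TRUE,
                       seed = 1L,
                       cohort_label = "cohort") {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  cn <- validate_cn_distribution(cn_distribution)
  if (!is.numeric(mean_fragment_length) || mean_fragment_length <= 0) {
    stop("`mean_fragment_length` must be > 0 (possibly Inf)", call. = FALSE)
  }
  stopifnot(ct_noise_sd >= 0, area_noise_cv >= 0, n_replicates >= 1,
            pcr_cycles >= 1, detection_threshold > 0, max_cycles > 0)
  structure(
    list(n_samples = as.integer(n_samples),
         cn_distribution = cn,
         input_model = input_model,
         mean_fragment_length = mean_fragment_length,
         ct_noise_sd = ct_noise_sd,
         area_noise_cv = area_noise_cv,
         n_replicates = as.integer(n_replicates),
         pcr_cycles = as.integer(pcr_cycles),
         detection_threshold = detection_threshold,
         max_cycles = max_cycles,
         template_poisson = isTRUE(template_poisson),
         seed = as.integer(seed),
         cohort_label = cohort_label),
    class = "sim_config"
  )
}

validate_cn_distribution <- function(cn_distribution) {
  if (is.null(names(cn_distribution)) ||
      anyNA(suppressWarnings(as.integer(names(cn_distribution))))) {
    stop("`cn_distribution` must be named by integer copy numbers",
         call. = FALSE)
  }
  k <- as.integer(names(cn_distribution))
  p <- as.numeric(cn_distribution)
  if (any(k < 0) || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("`cn_distribution` probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  setNames(p / sum(p), k)
}

#' Generate a cohort of samples with known copy numbers
#'
#' Draws each sample's true integer copy number from the configured
#' distribution and its per-reaction DNA input from the configured input
#' model; template integrity (mean fragment length) is shared by the cohort.
#' The result is the ground truth that downstream simulated assays measure.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sample_id`, `true_cn`, `input_mass`,
#'   `mean_fragment_length`, `cohort_label`; exactly
#'   `config$n_samples` rows, reproducible under `config$seed`.
#' @examples
#' make_cohort(sim_config(5, c("2" = 1), seed = 42))
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  cn_levels <- as.integer(names(config$cn_distribution))
  cn <- cn_levels[sample.int(length(cn_levels), n, replace = TRUE,
                             prob = config$cn_distribution)]
  im <- config$input_model
  input <- switch(im$type,
    normalized = rep(im$ng, n),
    lognormal = {
      mu <- log(im$mean_ng) - im$sdlog^2 / 2
      pmin(pmax(rlnorm(n, meanlog = mu, sdlog = im$sdlog), im$min_ng),
           im$max_ng)
    },
    stop("unknown input model type: ", im$type, call. = FALSE)
  )
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    true_cn = cn,
    input_mass = input,
    mean_fragment_length = config$mean_fragment_length,
    cohort_label = config$cohort_label
  )
}
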