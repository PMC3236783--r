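#' Describe a PCR assay
#'
#' An assay profile bundles the quantities that determine how an assay
#' responds to template: its per-cycle amplification efficiency, the length
#' of the product it amplifies (which sets its sensitivity to template
#' fragmentation), and its role in a copy-number experiment.
#'
#' @param name Assay label, e.g. `"PRELID1_qpcr"`.
#' @param efficiency Per-cycle amplification efficiency `E`, as a fraction:
#'   `E = 1` is perfect doubling, `E = 1.0823` is the 108.23% sometimes seen
#'   for real TaqMan assays. Must lie in (0, 1.2].
#' @param amplicon_length Length of the amplified product in base pairs
#'   (>= 50). For a PRT pair this is the full, pre-digestion product length,
#'   which is what template fragmentation acts on.
#' @param role One of `"qpcr_target"`, `"qpcr_reference"`, `"prt_pair"`.
#' @param intercept Optional Ct at one genome-copy equivalent of template.
#'   When `NULL` (default) it is derived from the simulation detection
#'   threshold, which only fixes the arbitrary absolute Ct scale.
#' @param paralog_length For `role = "prt_pair"`: length in base pairs of the
#'   distinguishable (e.g. restriction-digested) paralog fragment, kept as
#'   assay metadata. Required for PRT pairs.
#' @param reference_copies For `role = "prt_pair"`: diploid copy number of
#'   the invariant paralog locus (integer >= 1). Required for PRT pairs.
#'
#' @return An object of class `assay_profile`.
#' @examples
#' assay_profile("PRELID1_qpcr", efficiency = 1.0823, amplicon_length = 107,
#'               role = "qpcr_target")
#' @export
assay_profile <- function(name, efficiency, amplicon_length, role,
                          intercept = NULL,
                          paralog_length = NULL, reference_copies = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  role <- match.arg(role, c("qpcr_target", "qpcr_reference", "prt_pair"))
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 0 || efficiency > 1.2) {
    stop("`efficiency` must be a single value in (0, 1.2]", call. = FALSE)
  }
  if (!is.numeric(amplicon_length) || amplicon_length < 50) {
    stop("`amplicon_length` must be >= 50 bp", call. = FALSE)
  }
  if (role == "prt_pair") {
    if (is.null(paralog_length) || is.null(reference_copies)) {
      stop("a PRT pair requires `paralog_length` and `reference_copies`",
           call. = FALSE)
    }
    if (reference_copies < 1 || reference_copies != round(reference_copies)) {
      stop("`reference_copies` must be an integer >= 1", call. = FALSE)
    }
  }
  structure(
    list(name = name, efficiency = efficiency,
         amplicon_length = amplicon_length, intercept = intercept,
         role = role, paralog_length = paralog_length,
         reference_copies = reference_copies),
    class = "assay_profile"
  )
}

#' @export
print.assay_profile <- function(x, ...) {
  cat(sprintf("<assay_profile> %s [%s]\n", x$name, x$role))
  cat(sprintf("  efficiency: %.2f%%  amplicon: %d bp\n",
              100 * x$efficiency, as.integer(x$amplicon_length)))
  if (x$role == "prt_pair") {
    cat(sprintf("  paralog fragment: %d bp  reference copies: %d\n",
                as.integer(x$paralog_length), as.integer(x$reference_copies)))
  }
  invisible(x)
}

# Ct at a single genome-copy equivalent of template, on the arbitrary scale
# fixed by the detection threshold unless the assay pins its own intercept.
assay_intercept <- function(assay, detection_threshold) {
  if (!is.null(assay$intercept)) return(assay$intercept)
  log10(detection_threshold) / log10(1 + assay$efficiency)
}
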