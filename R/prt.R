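#' Per-sample peak-area ratios from a PRT peak table
#'
#' Computes the target/paralog area ratio per replicate, drops replicates
#' whose paralog peak is zero (reason code `ZERO_PARALOG_AREA`), and
#' averages the surviving ratios per sample. Samples with no usable
#' replicate are excluded with a warning and listed in the `excluded`
#' attribute.
#'
#' @param peak_table Tibble with columns `sample_id`, `replicate_index`,
#'   `area_target`, `area_paralog` (areas >= 0).
#' @return Tibble with columns `sample_id`, `ratio`, `n_replicates_used`;
#'   attribute `excluded` as in [delta_ct_table()].
#' @export
peak_ratios <- function(peak_table) {
  req <- c("sample_id", "replicate_index", "area_target", "area_paralog")
  miss <- setdiff(req, names(peak_table))
  if (length(miss)) {
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(peak_table$area_target < 0, na.rm = TRUE) ||
      any(peak_table$area_paralog < 0, na.rm = TRUE)) {
    stop("peak areas must be >= 0", call. = FALSE)
  }
  usable <- !is.na(peak_table$area_target) &
    !is.na(peak_table$area_paralog) & peak_table$area_paralog > 0
  agg <- peak_table |>
    dplyr::mutate(.usable = usable) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      ratio = mean(.data$area_target[.data$.usable] /
                     .data$area_paralog[.data$.usable]),
      n_replicates_used = sum(.data$.usable),
      .groups = "drop"
    )
  dropped <- agg$n_replicates_used == 0
  excluded <- tibble::tibble(sample_id = agg$sample_id[dropped],
                             reason = rep("ZERO_PARALOG_AREA", sum(dropped)))
  if (any(dropped)) {
    warning(sum(dropped),
            " sample(s) excluded: no replicate with a nonzero paralog peak",
            call. = FALSE)
  }
  out <- agg[!dropped, ]
  attr(out, "excluded") <- excluded
  out
}

#' Continuous copy number from peak-area ratios, anchored to the cohort mode
#'
#' Because the paralog locus carries a fixed `reference_copies` per diploid
#' genome, the expected area ratio is `true_cn / reference_copies`. The
#' cohort is calibrated so its median ratio maps exactly onto the modal
#' integer copy number, mirroring the calibration of the qPCR arm.
#'
#' @param records Output of [peak_ratios()] (>= 3 samples).
#' @param modal_cn Modal integer copy number of the population.
#' @param reference_copies Diploid copy number of the invariant paralog.
#' @return Tibble with columns `sample_id`, `continuous_cn`; the cohort
#'   median of `continuous_cn` equals `modal_cn` exactly.
#' @export
continuous_cn_prt <- function(records, modal_cn, reference_copies = 2) {
  stopifnot(modal_cn >= 0, reference_copies >= 1)
  if (nrow(records) < 3) {
    stop("cohort calibration requires >= 3 samples", call. = FALSE)
  }
  calibration <- median(records$ratio) / (modal_cn / reference_copies)
  tibble::tibble(sample_id = records$sample_id,
                 continuous_cn = reference_copies * records$ratio /
                   calibration)
}

#' Maximum-likelihood assignment of integer copy numbers
#'
#' Each continuous estimate `v` is scored against candidate integers
#' `k = 0..k_max` with a Gaussian likelihood centred on `k` whose standard
#' deviation grows affinely with the candidate,
#' `sigma(k) = sigma0 + cv * k`, reflecting the multiplicative noise of
#' both assays (absolute spread widens at higher copy number). The call is
#' the likelihood argmax (ties broken toward the smaller integer) and the
#' confidence is the called candidate's share of the summed likelihoods.
#' With `cv = 0` the rule reduces exactly to nearest-integer rounding with
#' half-points going down; with `cv > 0` the decision boundaries sit above
#' the half-integers.
#'
#' @param values Continuous copy-number estimates (finite, >= 0);
#'   non-finite entries are excluded with a warning.
#' @param sigma0 Baseline standard deviation at copy number 0 (> 0).
#' @param cv Per-copy increment of the standard deviation (>= 0).
#' @param k_max Largest candidate integer (>= 2).
#' @return Tibble with columns `value`, `predicted_cn`, `confidence`; one
#'   row per retained input value, in input order.
#' @examples
#' ml_assign_integer(c(1.2, 2.49, 2.6, 3.9))
#' @export
ml_assign_integer <- function(values, sigma0 = 0.05, cv = 0.05, k_max = 10) {
  stopifnot(sigma0 > 0, cv >= 0, k_max >= 2)
  bad <- !is.finite(values)
  if (any(bad)) {
    warning(sum(bad), " non-finite value(s) excluded from integer calling",
            call. = FALSE)
  }
  v <- values[!bad]
  k <- 0:k_max
  sigma_k <- sigma0 + cv * k
  # log-likelihood matrix, samples x candidates; normalise per row via the
  # max so confidences survive heavy underflow far from all candidates
  logd <- vapply(seq_along(k),
                 function(j) dnorm(v, mean = k[j], sd = sigma_k[j],
                                   log = TRUE),
                 numeric(length(v)))
  logd <- matrix(logd, nrow = length(v))
  pred <- max.col(logd, ties.method = "first") - 1L
  w <- exp(logd - apply(logd, 1, max))
  conf <- w[cbind(seq_along(v), pred + 1L)] / rowSums(w)
  tibble::tibble(value = v, predicted_cn = pred, confidence = conf)
}

#' Call integer copy numbers from a PRT peak table
#'
#' Full PRT calling chain: per-sample peak-area ratios ([peak_ratios()]),
#' modal-anchored continuous copy number ([continuous_cn_prt()]), then
#' maximum-likelihood integer assignment ([ml_assign_integer()]) -- the
#' same engine used by the qPCR arm.
#'
#' @inheritParams continuous_cn_prt
#' @inheritParams ml_assign_integer
#' @param peak_table PRT peak table (see [peak_ratios()]).
#' @return A calls tibble: `sample_id`, `continuous_cn`, `predicted_cn`,
#'   `confidence`, `method` (= `"prt"`).
#' @export
call_prt <- function(peak_table, modal_cn, reference_copies = 2,
                     sigma0 = 0.05, cv = 0.05, k_max = 10) {
  records <- peak_ratios(peak_table)
  cont <- continuous_cn_prt(records, modal_cn,
                            reference_copies = reference_copies)
  ml <- ml_assign_integer(cont$continuous_cn, sigma0 = sigma0, cv = cv,
                          k_max = k_max)
  tibble::tibble(sample_id = cont$sample_id,
                 continuous_cn = cont$continuous_cn,
                 predicted_cn = ml$predicted_cn,
                 confidence = ml$confidence,
                 method = "prt")
}
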