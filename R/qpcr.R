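#' Amplification efficiency from a dilution-curve slope
#'
#' For a standard curve of Ct against log10 input, the slope `m` (cycles per
#' decade of template, always negative for an amplifying assay) determines
#' the per-cycle efficiency as `E = 10^(-1/m) - 1`. A slope of -3.32193
#' corresponds to perfect doubling (`E = 1`).
#'
#' @param m Slope of Ct versus log10(input), cycles per decade (< 0).
#' @return Efficiency `E` as a fraction per cycle.
#' @seealso [slope_from_efficiency()] for the inverse.
#' @examples
#' efficiency_from_slope(-3.32193)  # ~1 (100%)
#' @export
efficiency_from_slope <- function(m) {
  if (any(!is.finite(m)) || any(m >= 0)) {
    stop("slope `m` must be finite and negative", call. = FALSE)
  }
  10^(-1 / m) - 1
}

#' @rdname efficiency_from_slope
#' @param e Efficiency as a fraction per cycle (> 0).
#' @export
slope_from_efficiency <- function(e) {
  if (any(e <= 0)) stop("efficiency must be positive", call. = FALSE)
  -1 / log10(1 + e)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 input over a dilution series; the
#' slope yields the assay's amplification efficiency and the R-squared is
#' the usual linearity quality check (well-behaved assays exceed 0.99 over
#' a four-log dilution range).
#'
#' @param dilution_series Data frame with columns `log10_input` (log10 ng
#'   of template) and `ct` (cycles); at least 3 distinct dilution points.
#' @return An object of class `standard_curve` with elements `slope`
#'   (cycles/decade), `intercept` (cycles), `r_squared`, `efficiency`
#'   and `n_points`.
#' @examples
#' ser <- data.frame(log10_input = 0:2, ct = c(30, 26.6781, 23.3562))
#' fit_standard_curve(ser)
#' @export
fit_standard_curve <- function(dilution_series) {
  req <- c("log10_input", "ct")
  miss <- setdiff(req, names(dilution_series))
  if (length(miss)) {
    stop("dilution series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(dilution_series[req])
  d <- dilution_series[ok, req]
  if (length(unique(d$log10_input)) < 3) {
    stop("need >= 3 distinct dilution points", call. = FALSE)
  }
  fit <- lm(ct ~ log10_input, data = d)
  m <- unname(coef(fit)[2])
  # R^2 from the sums of squares directly: summary.lm() warns on the exact
  # dilution series used for closed-form checks
  tss <- sum((d$ct - mean(d$ct))^2)
  rss <- sum(fit$residuals^2)
  structure(
    list(slope = m,
         intercept = unname(coef(fit)[1]),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         efficiency = efficiency_from_slope(m),
         n_points = nrow(d)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  slope: %.4f cycles/decade  intercept: %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  efficiency: %.2f%%  R^2: %.5f  (n = %d)\n",
              100 * x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' Per-sample delta-Ct from a replicated Ct table
#'
#' For every sample, the usable replicates (both Cts present) are averaged
#' per channel and the delta-Ct is `mean(ct_target) - mean(ct_reference)`.
#' Replicates with either Ct missing are dropped and counted; samples with
#' no usable replicate are excluded with a warning and listed in the
#' `excluded` attribute (reason code `NO_USABLE_REPLICATES`).
#'
#' @param ct_table Tibble with columns `sample_id`, `replicate_index`,
#'   `ct_target`, `ct_reference` and optionally `input_mass`.
#' @return Tibble with columns `sample_id`, `delta_ct`,
#'   `n_replicates_used`, `input_mass` (`NA` if absent from the input);
#'   attribute `excluded` is a tibble of dropped samples and reasons.
#' @export
delta_ct_table <- function(ct_table) {
  req <- c("sample_id", "replicate_index", "ct_target", "ct_reference")
  miss <- setdiff(req, names(ct_table))
  if (length(miss)) {
    stop("ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"input_mass" %in% names(ct_table)) ct_table$input_mass <- NA_real_
  usable <- !is.na(ct_table$ct_target) & !is.na(ct_table$ct_reference)
  agg <- ct_table |>
    dplyr::mutate(.usable = usable) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      delta_ct = mean(.data$ct_target[.data$.usable]) -
        mean(.data$ct_reference[.data$.usable]),
      n_replicates_used = sum(.data$.usable),
      input_mass = .data$input_mass[1],
      .groups = "drop"
    )
  dropped <- agg$n_replicates_used == 0
  excluded <- tibble::tibble(sample_id = agg$sample_id[dropped],
                             reason = rep("NO_USABLE_REPLICATES",
                                          sum(dropped)))
  if (any(dropped)) {
    warning(sum(dropped), " sample(s) excluded: no replicate with both Cts",
            call. = FALSE)
  }
  out <- agg[!dropped, ]
  attr(out, "excluded") <- excluded
  out
}

#' Continuous copy number from delta-Ct, anchored to the cohort mode
#'
#' Implements the delta-delta-Ct quantification used by standard
#' copy-number callers: relative quantity `2^(-delta_ct)` per sample,
#' calibrated so that the cohort median maps exactly onto the population's
#' modal integer copy number. The base-2 default deliberately encodes the
#' 100%-efficiency assumption of that method, which is what makes calls
#' sensitive to target/reference efficiency mismatch when input DNA varies;
#' pass `base = 1 + E` for an efficiency-corrected variant.
#'
#' @param records Output of [delta_ct_table()] (>= 3 samples; a cohort is
#'   required for calibration).
#' @param modal_cn Modal integer copy number of the population (e.g. 2 for
#'   most genes, 4 for the beta-defensin cluster).
#' @param base Exponential base relating delta-Ct to fold change; default 2.
#' @return Tibble with columns `sample_id`, `continuous_cn`, `input_mass`.
#'   The cohort median of `continuous_cn` equals `modal_cn` exactly.
#' @export
continuous_cn_qpcr <- function(records, modal_cn, base = 2) {
  stopifnot(modal_cn >= 0, base > 1)
  if (nrow(records) < 3) {
    stop("cohort calibration requires >= 3 samples", call. = FALSE)
  }
  rel <- base^(-records$delta_ct)
  cal <- median(rel)
  tibble::tibble(sample_id = records$sample_id,
                 continuous_cn = modal_cn * rel / cal,
                 input_mass = records$input_mass)
}

#' Predict the delta-Ct drift caused by unequal assay efficiencies
#'
#' On a dilution plot, an assay's Ct falls by `1/log10(1+E)` cycles per
#' decade of input; a more efficient assay has the shallower line. When the
#' target and reference efficiencies differ, the gap between the two lines
#' -- the delta-Ct -- therefore changes with input DNA amount:
#' `dct_per_decade = (-1/log10(1+e_target)) - (-1/log10(1+e_reference))`
#' cycles per tenfold input. Under base-2 (100%-efficiency) calling this
#' multiplies the called copy number by `2^(-dct_per_decade)` per decade:
#' a *more* efficient target than reference makes delta-Ct rise with input
#' and calls deflate (`cn_factor_per_decade < 1`); a more efficient
#' reference inflates calls at high input, the direction seen when cohorts
#' show copy number climbing with DNA concentration.
#'
#' @param e_target,e_reference Amplification efficiencies (> 0).
#' @return List with `dct_per_decade` (cycles per tenfold input) and
#'   `cn_factor_per_decade` (fold change of the called copy number per
#'   tenfold input).
#' @examples
#' predict_dct_drift(1.0823, 1.0228)  # |drift| ~ 0.129 cycles/decade
#' @export
predict_dct_drift <- function(e_target, e_reference) {
  if (e_target <= 0 || e_reference <= 0) {
    stop("efficiencies must be positive", call. = FALSE)
  }
  d <- slope_from_efficiency(e_target) - slope_from_efficiency(e_reference)
  list(dct_per_decade = d, cn_factor_per_decade = 2^(-d))
}

#' Correlation between input DNA amount and called copy number
#'
#' Pearson correlation (two-sided test) of continuous copy-number calls
#' against per-reaction input mass -- the diagnostic for input-driven
#' calling bias in a non-normalized cohort. A degenerate input (constant
#' calls or constant masses) is reported as `r = 0`, `p = 1` with
#' `degenerate = TRUE` rather than an error, so batch pipelines survive
#' constant-call cohorts.
#'
#' @param calls Data frame with columns `input_mass` and `continuous_cn`
#'   (e.g. from [continuous_cn_qpcr()]); n >= 3.
#' @return List with `pearson_r`, `p_value`, `n`, `degenerate`.
#' @export
input_cn_correlation <- function(calls) {
  req <- c("input_mass", "continuous_cn")
  miss <- setdiff(req, names(calls))
  if (length(miss)) {
    stop("calls lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(calls[req])
  x <- calls$input_mass[ok]
  y <- calls$continuous_cn[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(pearson_r = 0, p_value = 1, n = length(x),
                degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), degenerate = FALSE)
}

#' Call integer copy numbers from a qPCR Ct table
#'
#' Full qPCR calling chain: per-sample delta-Ct ([delta_ct_table()]),
#' modal-anchored continuous copy number ([continuous_cn_qpcr()]), then
#' maximum-likelihood integer assignment ([ml_assign_integer()]).
#'
#' @inheritParams continuous_cn_qpcr
#' @inheritParams ml_assign_integer
#' @param ct_table Replicated Ct table (see [delta_ct_table()]).
#' @return A calls tibble: `sample_id`, `continuous_cn`, `predicted_cn`,
#'   `confidence`, `method` (= `"qpcr"`), plus `input_mass`.
#' @export
call_qpcr <- function(ct_table, modal_cn, base = 2,
                      sigma0 = 0.05, cv = 0.05, k_max = 10) {
  records <- delta_ct_table(ct_table)
  cont <- continuous_cn_qpcr(records, modal_cn, base = base)
  ml <- ml_assign_integer(cont$continuous_cn, sigma0 = sigma0, cv = cv,
                          k_max = k_max)
  tibble::tibble(sample_id = cont$sample_id,
                 continuous_cn = cont$continuous_cn,
                 predicted_cn = ml$predicted_cn,
                 confidence = ml$confidence,
                 method = "qpcr",
                 input_mass = cont$input_mass)
}
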