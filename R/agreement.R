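#' Cross-tabulate integer calls from two methods
#'
#' Builds the (k_max+1) x (k_max+1) concordance matrix of two callers'
#' integer predictions, with method A on the rows and method B on the
#' columns. Only samples present in both call sets contribute; the number
#' dropped from either side is recorded in the `dropped` attribute.
#'
#' @param calls_a,calls_b Calls tibbles with `sample_id` and `predicted_cn`
#'   (e.g. from [call_qpcr()] / [call_prt()]).
#' @param method_a,method_b Labels; default to the `method` column when
#'   present. Orientation is explicit in the object, not positional.
#' @param k_max Largest copy number indexed; defaults to the largest
#'   prediction observed.
#' @return An object of class `concordance_matrix`: list with `counts`
#'   (integer matrix, dimnames = copy numbers 0..k_max), `method_a`,
#'   `method_b`, `n_total`.
#' @export
concordance_matrix <- function(calls_a, calls_b,
                               method_a = NULL, method_b = NULL,
                               k_max = NULL) {
  lab <- function(calls, fallback) {
    if (!is.null(calls$method)) as.character(calls$method[1]) else fallback
  }
  if (is.null(method_a)) method_a <- lab(calls_a, "method_a")
  if (is.null(method_b)) method_b <- lab(calls_b, "method_b")
  common <- intersect(calls_a$sample_id, calls_b$sample_id)
  if (length(common) == 0) {
    stop("no samples shared between the two call sets", call. = FALSE)
  }
  a <- calls_a$predicted_cn[match(common, calls_a$sample_id)]
  b <- calls_b$predicted_cn[match(common, calls_b$sample_id)]
  if (is.null(k_max)) k_max <- max(a, b)
  lev <- 0:k_max
  counts <- table(factor(a, levels = lev), factor(b, levels = lev))
  counts <- matrix(as.integer(counts), nrow = length(lev),
                   dimnames = list(lev, lev))
  structure(
    list(counts = counts, method_a = method_a, method_b = method_b,
         n_total = sum(counts)),
    class = "concordance_matrix",
    dropped = (nrow(calls_a) - length(common)) +
      (nrow(calls_b) - length(common))
  )
}

#' Build a concordance matrix from a pre-tabulated count grid
#'
#' For published concordance tables that arrive as a count grid rather than
#' per-sample calls (row and column names are the integer copy numbers).
#'
#' @param counts Square integer matrix with copy-number dimnames; rows are
#'   method A, columns method B.
#' @inheritParams concordance_matrix
#' @return A `concordance_matrix`.
#' @export
as_concordance_matrix <- function(counts, method_a = "method_a",
                                  method_b = "method_b") {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry copy-number dimnames", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, method_a = method_a, method_b = method_b,
         n_total = sum(counts)),
    class = "concordance_matrix"
  )
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("<concordance_matrix> rows: %s  columns: %s  (n = %d)\n",
              x$method_a, x$method_b, x$n_total))
  print(x$counts)
  invisible(x)
}

#' Concordance rates from a cross-tabulation
#'
#' Fractions of samples on, above and below the diagonal of a
#' [concordance_matrix()]. "Above the diagonal" means the column method
#' (method B) called the higher copy number. The fractions are exact
#' rationals of the cell counts and sum to 1; rounding to whole percent is
#' left to the reporting layer.
#'
#' @param matrix A `concordance_matrix`.
#' @return List with `frac_same`, `frac_b_higher`, `frac_b_lower`.
#' @export
concordance_rates <- function(matrix) {
  stopifnot(inherits(matrix, "concordance_matrix"))
  if (matrix$n_total == 0) stop("empty concordance matrix", call. = FALSE)
  cn_row <- as.numeric(rownames(matrix$counts))
  cn_col <- as.numeric(colnames(matrix$counts))
  rel <- outer(cn_row, cn_col, function(i, j) sign(j - i))
  n <- matrix$n_total
  list(frac_same = sum(matrix$counts[rel == 0]) / n,
       frac_b_higher = sum(matrix$counts[rel > 0]) / n,
       frac_b_lower = sum(matrix$counts[rel < 0]) / n)
}

#' Reproducibility of repeated runs of one method
#'
#' Pairs two runs by sample, reporting the fraction of identical integer
#' predictions and the Pearson correlation of the continuous estimates --
#' the two reproducibility summaries used when an assay is repeated on the
#' same cohort.
#'
#' @param calls_run1,calls_run2 Calls tibbles with `sample_id`,
#'   `predicted_cn` and `continuous_cn`.
#' @return List with `frac_same`, `pearson_r`, `n`.
#' @export
replicate_agreement <- function(calls_run1, calls_run2) {
  common <- intersect(calls_run1$sample_id, calls_run2$sample_id)
  if (length(common) == 0) stop("no paired samples", call. = FALSE)
  i1 <- match(common, calls_run1$sample_id)
  i2 <- match(common, calls_run2$sample_id)
  r <- if (sd(calls_run1$continuous_cn[i1]) == 0 ||
           sd(calls_run2$continuous_cn[i2]) == 0) {
    NA_real_
  } else {
    cor(calls_run1$continuous_cn[i1], calls_run2$continuous_cn[i2])
  }
  list(frac_same = mean(calls_run1$predicted_cn[i1] ==
                          calls_run2$predicted_cn[i2]),
       pearson_r = r,
       n = length(common))
}

#' Bland-Altman agreement between two continuous measurements
#'
#' Per-pair differences (B minus A) summarised by their mean, the 1.96-SD
#' limits of agreement, the fraction of pairs whose absolute difference is
#' below one copy, and the Pearson correlation of the paired values.
#'
#' @param values_a,values_b Paired continuous copy-number estimates
#'   (equal length, n >= 2).
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `frac_abs_diff_lt_1`, `pearson_r`, `n`, plus vectors `mean_pair` and
#'   `diff` for plotting.
#' @export
bland_altman <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  ok <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  d <- b - a
  m <- mean(d)
  s <- sd(d)
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       frac_abs_diff_lt_1 = mean(abs(d) < 1),
       pearson_r = r, n = length(a),
       mean_pair = (a + b) / 2, diff = d)
}

#' Chi-squared comparison of two predicted-copy-number distributions
#'
#' Pearson chi-squared test on the 2 x K table of integer-call frequencies
#' from two call sets. Sparse copy-number categories are pooled with their
#' inward neighbour, starting from whichever cell has the smallest expected
#' count, until every expected count reaches `min_expected`; the test then
#' has `K_pooled - 1` degrees of freedom.
#'
#' @param calls_a,calls_b Integer prediction vectors, or calls tibbles with
#'   a `predicted_cn` column.
#' @param min_expected Minimum expected count per cell after pooling
#'   (default 5).
#' @return List with `chi2`, `df`, `p_value` and the pooled `table`
#'   (categories as column names, pooled ranges shown as `"lo-hi"`).
#' @export
distribution_chi2 <- function(calls_a, calls_b, min_expected = 5) {
  get_pred <- function(x) {
    if (is.data.frame(x)) x$predicted_cn else x
  }
  a <- get_pred(calls_a); b <- get_pred(calls_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both call sets must be non-empty", call. = FALSE)
  }
  lev <- seq(min(a, b), max(a, b))
  tab <- rbind(a = tabulate(factor(a, levels = lev), nbins = length(lev)),
               b = tabulate(factor(b, levels = lev), nbins = length(lev)))
  colnames(tab) <- as.character(lev)
  lo <- lev; hi <- lev

  expected <- function(t) outer(rowSums(t), colSums(t)) / sum(t)
  while (ncol(tab) > 2 && min(expected(tab)) < min_expected) {
    j <- which.min(apply(expected(tab), 2, min))
    into <- if (j == 1) 2L
            else if (j == ncol(tab)) ncol(tab) - 1L
            else if (j <= ncol(tab) / 2) j + 1L else j - 1L
    tab[, into] <- tab[, into] + tab[, j]
    lo[into] <- min(lo[into], lo[j]); hi[into] <- max(hi[into], hi[j])
    tab <- tab[, -j, drop = FALSE]
    lo <- lo[-j]; hi <- hi[-j]
  }
  if (ncol(tab) < 2) stop("fewer than 2 categories survive pooling",
                          call. = FALSE)
  colnames(tab) <- ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi))
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab)
}
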