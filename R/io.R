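#' Read and write the package's CSV tables
#'
#' All tables travel as headered, comma-separated, UTF-8 CSV with `.` as
#' the decimal separator; missing measurements (e.g. a Ct with no
#' amplification) are empty fields. Readers validate the schema (a missing
#' column is reported by name) and every numeric cell (a non-numeric cell
#' is reported with its row number).
#'
#' @param path File path.
#' @return `read_ct_table()`: a Ct table tibble (`sample_id`,
#'   `replicate_index`, `ct_target`, `ct_reference`, `input_mass`);
#'   `read_peak_table()`: a peak table tibble (`sample_id`,
#'   `replicate_index`, `area_target`, `area_paralog`).
#' @name table_io
NULL

read_checked_csv <- function(path, numeric_cols, required,
                             optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- suppressMessages(
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE)
  )
  if (nrow(df) == 0) stop("empty table: ", path, call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[intersect(c(required, optional), names(df))]
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(raw != "" & is.na(val))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ",
           bad[1], " of ", basename(path), ": '", raw[bad[1]], "'",
           call. = FALSE)
    }
    df[[col]] <- val
  }
  tibble::as_tibble(df)
}

#' @rdname table_io
#' @export
read_ct_table <- function(path) {
  tab <- read_checked_csv(
    path,
    numeric_cols = c("replicate_index", "ct_target", "ct_reference",
                     "input_mass"),
    required = c("sample_id", "replicate_index", "ct_target",
                 "ct_reference"),
    optional = "input_mass"
  )
  if (!"input_mass" %in% names(tab)) tab$input_mass <- NA_real_
  present <- !is.na(tab$ct_target) | !is.na(tab$ct_reference)
  out_of_range <- present &
    ((!is.na(tab$ct_target) & (tab$ct_target <= 0 | tab$ct_target > 40)) |
     (!is.na(tab$ct_reference) &
        (tab$ct_reference <= 0 | tab$ct_reference > 40)))
  if (any(out_of_range)) {
    warning(sum(out_of_range), " row(s) carry Ct values outside (0, 40]",
            call. = FALSE)
  }
  tab
}

#' @rdname table_io
#' @export
read_peak_table <- function(path) {
  read_checked_csv(
    path,
    numeric_cols = c("replicate_index", "area_target", "area_paralog"),
    required = c("sample_id", "replicate_index", "area_target",
                 "area_paralog")
  )
}

#' Read a pre-tabulated concordance grid
#'
#' Accepts a published cross-tabulation as CSV: the first column holds the
#' row method's copy numbers, the header row the column method's copy
#' numbers, and the body the counts (empty cells count as zero).
#'
#' @param path CSV file path.
#' @param method_a,method_b Labels for the row and column methods.
#' @return A [as_concordance_matrix()] object.
#' @export
read_matrix <- function(path, method_a = "method_a", method_b = "method_b") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- suppressMessages(
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE)
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("matrix file must have row labels plus >= 1 count column",
         call. = FALSE)
  }
  row_cn <- df[[1]]
  body <- as.matrix(df[-1])
  body[body == ""] <- "0"
  val <- suppressWarnings(as.numeric(body))
  if (anyNA(val)) stop("non-numeric count in ", basename(path),
                       call. = FALSE)
  counts <- matrix(val, nrow = nrow(df),
                   dimnames = list(row_cn, colnames(df)[-1]))
  if (nrow(counts) != ncol(counts) ||
      !identical(rownames(counts), colnames(counts))) {
    # pad to the union of row/column copy numbers so the grid is square
    cn <- as.character(sort(unique(as.integer(c(rownames(counts),
                                                colnames(counts))))))
    full <- matrix(0L, length(cn), length(cn), dimnames = list(cn, cn))
    full[rownames(counts), colnames(counts)] <- counts
    counts <- full
  }
  as_concordance_matrix(counts, method_a = method_a, method_b = method_b)
}

#' @rdname table_io
#' @param x Table to write.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}
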