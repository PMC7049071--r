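#' Read a covariate-by-group counts CSV
#'
#' Expects a header row, a first column of covariate level labels, and one
#' column per treatment group holding non-negative integer counts. Row and
#' column order in the file is preserved. The packaged example table
#' (glucose category by neighborhood-deprivation/age group, 93,583
#' outpatients) ships at
#' `system.file("extdata", "glucose_counts.csv", package = "jsdbalance")`.
#'
#' @param path Path to a CSV file.
#' @return A [balance_table()].
#' @examples
#' path <- system.file("extdata", "glucose_counts.csv", package = "jsdbalance")
#' read_counts_csv(path)
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Counts file not found: %s", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 3L) {
    abort_validation(sprintf("%s: need a level column plus >= 2 group columns.", path))
  }
  counts <- as.data.frame(df)
  for (j in 2:ncol(counts)) {
    val <- suppressWarnings(as.numeric(counts[[j]]))
    bad <- which(is.na(val) | val < 0 | val != round(val))
    if (length(bad)) {
      abort_validation(sprintf(
        "%s: cell at row %d, column '%s' is not a non-negative integer.",
        path, bad[1], names(counts)[j]
      ))
    }
    counts[[j]] <- as.integer(val)
  }
  balance_table(counts)
}

#' Write a balance table as a counts CSV
#'
#' Inverse of [read_counts_csv()]: the written file round-trips to an
#' identical table.
#'
#' @param x A [balance_table()] (or anything coercible to one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(x, path) {
  tab <- as_balance_table(x)
  readr::write_csv(as_tibble.balance_table(tab), path)
  invisible(path)
}

#' Read subject-level records from a long-format CSV
#'
#' One row per subject, with a treatment-group column and a covariate
#' column. Rows with a missing covariate value are excluded complete-case
#' style; the number of exclusions is reported via a message and recorded
#' in the `n_excluded` attribute. Missing group labels are an error.
#'
#' @param path Path to a CSV file.
#' @param group_col,covariate_col Column names (strings) in the file.
#' @param kind `"categorical"` or `"continuous"`. For continuous records
#'   every retained value must parse as a finite number; a non-numeric
#'   value is an error naming the offending line.
#' @return A tibble of class `"long_records"` with columns `group` and
#'   `covariate`, attributes `kind` and `n_excluded`.
#' @seealso [tabulate_records()]
#' @export
read_long_csv <- function(path, group_col, covariate_col,
                          kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort_validation(sprintf("Records file not found: %s", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  for (col in c(group_col, covariate_col)) {
    if (!col %in% names(df)) {
      abort_validation(sprintf("%s: column '%s' not found.", path, col))
    }
  }
  g <- df[[group_col]]
  v <- df[[covariate_col]]
  if (anyNA(g) || any(g == "")) {
    abort_validation(sprintf("%s: missing treatment-group labels.", path))
  }
  miss <- is.na(v) | v == ""
  n_excluded <- sum(miss)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "Excluded %d record(s) with missing covariate values.", n_excluded
    ))
  }
  g <- g[!miss]
  v <- v[!miss]
  if (kind == "continuous") {
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      line <- which(!miss)[bad[1]] + 1L # header is line 1
      abort_validation(sprintf(
        "%s: line %d: covariate value '%s' is not a finite number.",
        path, line, v[bad[1]]
      ))
    }
    v <- num
  }
  out <- tibble::tibble(group = g, covariate = v)
  attr(out, "kind") <- kind
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("long_records", class(out))
  out
}

#' Cross-tabulate subject-level records into a balance table
#'
#' Categorical records are counted into a level-by-group table (level
#' order = first appearance); continuous records are delegated to
#' [bin_groups()], for which binning controls must be supplied.
#'
#' @param records A `"long_records"` tibble from [read_long_csv()], or any
#'   data frame with `group` and `covariate` columns (the covariate's
#'   type then decides its kind).
#' @param n_bins,strategy Binning controls, required when the records are
#'   continuous and rejected when they are categorical.
#' @return A [balance_table()].
#' @export
tabulate_records <- function(records, n_bins = NULL,
                             strategy = c("equal_width", "quantile")) {
  if (!is.data.frame(records) || !all(c("group", "covariate") %in% names(records))) {
    abort_validation("`records` must have `group` and `covariate` columns.")
  }
  kind <- attr(records, "kind") %||%
    if (is.numeric(records$covariate)) "continuous" else "categorical"
  if (kind == "continuous") {
    if (is.null(n_bins)) {
      abort_validation("Continuous records require `n_bins` for binning.")
    }
    bin_groups(records, group, covariate,
      n_bins = n_bins, strategy = match.arg(strategy)
    )
  } else {
    if (!is.null(n_bins)) {
      abort_validation("`n_bins` only applies to continuous records.")
    }
    cross_tabulate(as.character(records$group), records$covariate)
  }
}

#' Render a balance report
#'
#' Produces a deterministic report of the balance analysis: the group and
#' common distributions, the cell decomposition with group and level
#' totals, the overall JSD, the maximum possible JSD, and the normalized
#' ratio. Output is byte-identical for identical inputs.
#'
#' Displayed values are rounded to 4 decimal places while totals are
#' computed from unrounded cells, so rounded rows and columns need not sum
#' exactly to the rounded totals; the text report carries a note to that
#' effect.
#'
#' @param x A [jsd_balance()] fit, or anything coercible to a
#'   [balance_table()].
#' @param format `"text"` (a human-readable report, one string per line),
#'   `"csv"` (the long cell-decomposition table as CSV text), or `"json"`
#'   (full-precision machine-readable report).
#' @return A character vector of report lines (`"text"`) or a single
#'   string (`"csv"`, `"json"`).
#' @examples
#' counts <- system.file("extdata", "glucose_counts.csv", package = "jsdbalance")
#' cat(render_report(jsd_balance(read_counts_csv(counts))), sep = "\n")
#' @export
render_report <- function(x, format = c("text", "csv", "json")) {
  format <- match.arg(format)
  fit <- if (inherits(x, "jsd_balance")) x else jsd_balance(x)
  switch(format,
    text = render_text_report(fit),
    csv = readr::format_csv(decompose_jsd(fit)),
    json = as.character(jsonlite::toJSON(
      list(
        overall_jsd_bits = fit$jsd_bits,
        max_jsd_bits = fit$max_jsd_bits,
        normalized_jsd = fit$normalized_jsd,
        n_subjects = fit$n_subjects,
        levels = rownames(fit$table),
        groups = colnames(fit$table),
        counts = unclass(fit$table),
        profiles = fit$profiles,
        common = unname(fit$common),
        cells = fit$cell,
        group_totals = unname(fit$group_totals),
        level_totals = unname(fit$level_totals)
      ),
      digits = NA, auto_unbox = TRUE
    ))
  )
}

render_text_report <- function(fit) {
  num <- function(v) formatC(v, format = "f", digits = 4, width = 14)
  lab <- function(s) formatC(s, width = 12, flag = "-")
  groups <- colnames(fit$table)
  head_row <- paste0(lab("level"), paste(formatC(groups, width = 14), collapse = ""))
  prof_rows <- vapply(seq_len(nrow(fit$table)), function(i) {
    paste0(
      lab(rownames(fit$table)[i]),
      paste(num(fit$profiles[i, ]), collapse = ""),
      num(fit$common[i])
    )
  }, character(1))
  cell_rows <- vapply(seq_len(nrow(fit$table)), function(i) {
    paste0(
      lab(rownames(fit$table)[i]),
      paste(num(fit$cell[i, ]), collapse = ""),
      num(fit$level_totals[i])
    )
  }, character(1))
  c(
    "Jensen-Shannon divergence balance report",
    "========================================",
    sprintf(
      "Subjects: %d   Groups: %d   Covariate levels: %d",
      fit$n_subjects, ncol(fit$table), nrow(fit$table)
    ),
    "",
    "Group covariate distributions (common = unweighted mean):",
    paste0(head_row, formatC("common", width = 14)),
    prof_rows,
    "",
    "Cell contributions to the JSD (bits):",
    paste0(head_row, formatC("total", width = 14)),
    cell_rows,
    paste0(
      lab("total"),
      paste(num(fit$group_totals), collapse = ""),
      num(fit$jsd_bits)
    ),
    "Note: cells are displayed rounded to 4 decimals; rounded rows and",
    "columns may not sum exactly to the rounded totals.",
    "",
    sprintf("Overall JSD: %.4f bits", fit$jsd_bits),
    sprintf(
      "Maximum possible JSD for %d groups: %.4f bits",
      ncol(fit$table), fit$max_jsd_bits
    ),
    sprintf("Normalized JSD (overall / maximum): %.4f", fit$normalized_jsd),
    "No fixed cut-point defines acceptable imbalance; weigh the JSD against",
    "the covariate's potential to affect the outcome."
  )
}
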