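#' Build a covariate-level by treatment-group count table
#'
#' A `balance_table` is the contingency table at the heart of the balance
#' workflow: one row per covariate level, one column per treatment group,
#' integer subject counts in the cells. It is stored as an integer matrix
#' with level/group dimnames and carries class `"balance_table"`.
#'
#' Covariate levels with zero count in every group carry no information
#' (their mixture probability would be 0/0) and are dropped with a warning.
#'
#' @param x A numeric matrix of counts (rows = covariate levels, columns =
#'   groups), or a data frame whose first column holds the level labels and
#'   whose remaining columns hold one group each, as read from a counts CSV.
#' @param levels,groups Optional label vectors overriding the dimnames of a
#'   matrix input.
#' @return A `balance_table` object.
#' @examples
#' balance_table(matrix(c(10, 5, 8, 7), 2,
#'   dimnames = list(c("low", "high"), c("ctrl", "trt"))
#' ))
#' @seealso [jsd_balance()], [read_counts_csv()], [bin_groups()]
#' @export
balance_table <- function(x, levels = NULL, groups = NULL) {
  if (inherits(x, "balance_table")) {
    return(x)
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 3L) {
      abort_validation("A counts data frame needs a level column plus >= 2 group columns.")
    }
    levels <- levels %||% as.character(x[[1]])
    groups <- groups %||% names(x)[-1]
    x <- as.matrix(x[-1])
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_validation("`x` must be a numeric count matrix or a counts data frame.")
  }
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    bad <- which(is.na(x) | !is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)[1, ]
    abort_validation(sprintf(
      "Counts must be non-negative integers; offending cell at row %d, column %d.",
      bad[1], bad[2]
    ))
  }
  levels <- levels %||% rownames(x) %||% paste0("level_", seq_len(nrow(x)))
  groups <- groups %||% colnames(x) %||% paste0("group_", seq_len(ncol(x)))
  if (anyDuplicated(levels)) abort_validation("Covariate level names must be unique.")
  if (anyDuplicated(groups)) abort_validation("Group names must be unique.")
  dimnames(x) <- list(as.character(levels), as.character(groups))
  if (ncol(x) < 2L) abort_validation("A balance table needs at least 2 treatment groups.")
  empty <- rowSums(x) == 0
  if (any(empty)) {
    warn(sprintf(
      "Dropping covariate level(s) with zero count in every group: %s",
      paste(rownames(x)[empty], collapse = ", ")
    ))
    x <- x[!empty, , drop = FALSE]
  }
  if (nrow(x) < 2L) abort_validation("A balance table needs at least 2 covariate levels.")
  zero_col <- colSums(x) == 0
  if (any(zero_col)) {
    abort_validation(sprintf(
      "Group(s) with zero total count: %s", paste(colnames(x)[zero_col], collapse = ", ")
    ))
  }
  structure(x, class = c("balance_table", class(x)))
}

#' @export
print.balance_table <- function(x, ...) {
  cat(sprintf(
    "Balance table: %d covariate levels x %d groups, %d subjects\n",
    nrow(x), ncol(x), sum(x)
  ))
  print(unclass(x))
  invisible(x)
}

#' @export
as_tibble.balance_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)), rownames = "level")
}

# Accept a balance_table, count matrix, counts data frame, or an existing fit.
as_balance_table <- function(x) {
  if (inherits(x, "jsd_balance")) {
    return(x$table)
  }
  balance_table(x)
}
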