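#' Jensen-Shannon divergence balance diagnostic
#'
#' Fits the JSD balance statistic for a covariate observed across two or
#' more treatment groups. Each group's covariate distribution
#' \eqn{p_k(C)} is estimated by normalizing its column of counts; the
#' common distribution \eqn{\tilde p(C)} is the *unweighted* mean of the
#' group distributions (group sample sizes do not weight the mixture); and
#' the statistic is the average relative entropy from the mixture to the
#' groups,
#' \deqn{\mathrm{JSD} = \frac{1}{N} \sum_k D(p_k(C) \,\|\, \tilde p(C)),}
#' in bits. Because the JSD is an expectation it decomposes additively into
#' per-cell terms \eqn{(1/N)\, p_k(c_i) \log_2(p_k(c_i)/\tilde p(c_i))},
#' whose column and row sums give treatment-group and covariate-level
#' contributions; the fitted object stores the full decomposition.
#'
#' The statistic is a function of the group proportions only, so it is
#' insensitive to sample size: rescaling any group's counts leaves every
#' output unchanged. It is zero exactly when all group distributions
#' coincide and is bounded by [max_jsd()] `= log2(N)` bits. No threshold
#' for "acceptable" imbalance is defined: there is no natural cut-point,
#' and how much imbalance matters depends on the covariate's potential to
#' affect the outcome.
#'
#' @param data One of: a [balance_table()] (or count matrix / counts data
#'   frame); or a subject-level data frame, one row per subject, in which
#'   case `group` and `covariate` select columns.
#' @param group,covariate Unquoted column names used when `data` is
#'   subject-level: the treatment-group label and the covariate value. A
#'   factor or character covariate is cross-tabulated (level order = first
#'   appearance, or factor level order); a numeric covariate is binned via
#'   [bin_groups()].
#' @param count Optional unquoted column of pre-aggregated cell counts,
#'   when `data` holds one row per (level, group) cell rather than one row
#'   per subject.
#' @param n_bins,bin_strategy Binning controls passed to [bin_groups()]
#'   for a numeric covariate; ignored otherwise.
#'
#' @return An object of class `"jsd_balance"`: a list with elements
#'   `table` (the [balance_table()]), `profiles` (levels x groups matrix of
#'   group distributions), `common` (the mixture distribution), `cell`
#'   (levels x groups matrix of bit contributions), `group_totals`,
#'   `level_totals`, `jsd_bits`, `max_jsd_bits`, `normalized_jsd` (the
#'   ratio `jsd_bits / max_jsd_bits`, a convenience rescaling to `[0, 1]`,
#'   not part of the original statistic), and `n_subjects`.
#'   Methods: [tidy()][tidy.jsd_balance()], [glance()][glance.jsd_balance()],
#'   [autoplot()][autoplot.jsd_balance()], `print()`.
#'
#' @examples
#' counts <- matrix(
#'   c(7191, 1025, 1715, 3637, 835, 685, 64265, 7298, 6932),
#'   nrow = 3,
#'   dimnames = list(
#'     c("<109", "109-125", ">125"),
#'     c("Disadvantaged", "Elderly", "Reference")
#'   )
#' )
#' fit <- jsd_balance(counts)
#' fit$jsd_bits
#' glance(fit)
#' tidy(fit)
#' @export
jsd_balance <- function(data, group = NULL, covariate = NULL, count = NULL,
                        n_bins = 10, bin_strategy = c("equal_width", "quantile")) {
  group <- enquo(group)
  covariate <- enquo(covariate)
  count <- enquo(count)
  if (is.data.frame(data) && !quo_is_null(group)) {
    g <- as.character(eval_tidy(group, data))
    if (anyNA(g)) abort_validation("Missing treatment-group labels are not allowed.")
    if (quo_is_null(covariate)) {
      abort_validation("Supply `covariate` together with `group`.")
    }
    v <- eval_tidy(covariate, data)
    if (!quo_is_null(count)) {
      cnt <- eval_tidy(count, data)
      tab <- cross_tabulate(g, as.character(v), weights = cnt)
    } else if (is.numeric(v)) {
      df <- tibble::tibble(group = g, value = v)
      tab <- bin_groups(df, group, value,
        n_bins = n_bins, strategy = match.arg(bin_strategy)
      )
    } else {
      tab <- cross_tabulate(g, v)
    }
  } else {
    tab <- as_balance_table(data)
  }
  fit_jsd_table(tab)
}

# Cross-tabulate subject-level (or weighted cell-level) records.
# Level order: factor levels if a factor, otherwise first appearance.
cross_tabulate <- function(group, value, weights = NULL) {
  if (anyNA(value)) abort_validation("Missing covariate values must be excluded before tabulation.")
  lev <- if (is.factor(value)) levels(value) else unique(as.character(value))
  grp <- unique(group)
  value <- as.character(value)
  weights <- weights %||% rep(1L, length(value))
  if (any(weights < 0) || any(weights != round(weights))) {
    abort_validation("Cell counts must be non-negative integers.")
  }
  m <- matrix(0L, nrow = length(lev), ncol = length(grp), dimnames = list(lev, grp))
  for (i in seq_along(value)) {
    m[value[i], group[i]] <- m[value[i], group[i]] + as.integer(weights[i])
  }
  balance_table(m)
}

fit_jsd_table <- function(tab) {
  tab <- as_balance_table(tab)
  n <- ncol(tab)
  profiles <- sweep(unclass(tab), 2, colSums(tab), "/")
  common <- rowMeans(profiles)
  cell <- matrix(0, nrow = nrow(tab), ncol = n, dimnames = dimnames(tab))
  pos <- profiles > 0
  cell[pos] <- (1 / n) * profiles[pos] * log2(sweep(profiles, 1, common, "/")[pos])
  overall <- sum(cell)
  structure(
    list(
      table = tab,
      profiles = profiles,
      common = common,
      cell = cell,
      group_totals = colSums(cell),
      level_totals = rowSums(cell),
      jsd_bits = overall,
      max_jsd_bits = log2(n),
      normalized_jsd = overall / log2(n),
      n_subjects = sum(tab)
    ),
    class = "jsd_balance"
  )
}

#' Per-group and common covariate distributions
#'
#' Normalizes each treatment group's counts into a probability
#' distribution over the covariate levels and appends the common
#' (mixture) distribution, the unweighted mean of the group distributions.
#' This is the table a balance report prints alongside the decomposition.
#'
#' @param x A [jsd_balance()] fit, a [balance_table()], or anything
#'   coercible to one (count matrix, counts data frame).
#' @return A tibble with one row per covariate level: `level`, one column
#'   per group, and `common`.
#' @examples
#' group_profiles(matrix(c(8, 2, 5, 5), 2,
#'   dimnames = list(c("low", "high"), c("A", "B"))
#' ))
#' @export
group_profiles <- function(x) {
  fit <- if (inherits(x, "jsd_balance")) x else fit_jsd_table(x)
  out <- tibble::as_tibble(as.data.frame(fit$profiles), rownames = "level")
  out$common <- unname(fit$common)
  out
}

#' Decompose the JSD into cell contributions
#'
#' Returns the additive decomposition of the balance statistic: one row
#' per (covariate level, treatment group) cell with the group probability,
#' the common probability, and the cell's contribution
#' \eqn{(1/N)\, p_k(c_i) \log_2(p_k(c_i)/\tilde p(c_i))} in bits. Cells
#' may be negative (a group under-represented at a level relative to the
#' mixture), but every group total and level total is non-negative, and
#' the grand sum is the overall JSD.
#'
#' @inheritParams group_profiles
#' @return A tibble with columns `level`, `group`, `p_group`, `p_common`,
#'   `bits`, in level-major order. Equivalent to [tidy()] on the fit.
#' @seealso [group_contributions()], [level_contributions()],
#'   [rank_contributions()]
#' @export
decompose_jsd <- function(x) {
  fit <- if (inherits(x, "jsd_balance")) x else fit_jsd_table(x)
  tibble::tibble(
    level = rep(rownames(fit$cell), times = ncol(fit$cell)),
    group = rep(colnames(fit$cell), each = nrow(fit$cell)),
    p_group = as.vector(fit$profiles),
    p_common = rep(unname(fit$common), times = ncol(fit$cell)),
    bits = as.vector(fit$cell)
  )
}

#' Treatment-group totals of the JSD decomposition
#'
#' Each group's total is \eqn{(1/N) D(p_k \| \tilde p)}, the group's share
#' of the overall statistic; totals are non-negative and sum to the JSD.
#'
#' @inheritParams group_profiles
#' @return A tibble with columns `group`, `bits`.
#' @export
group_contributions <- function(x) {
  fit <- if (inherits(x, "jsd_balance")) x else fit_jsd_table(x)
  tibble::tibble(group = names(fit$group_totals), bits = unname(fit$group_totals))
}

#' Covariate-level totals of the JSD decomposition
#'
#' Row sums of the cell decomposition: regions of the covariate space
#' exhibiting the greatest imbalance across groups. Non-negative (by the
#' log-sum inequality, since the mixture is the mean of the groups) and
#' summing to the overall JSD.
#'
#' @inheritParams group_profiles
#' @return A tibble with columns `level`, `bits`.
#' @export
level_contributions <- function(x) {
  fit <- if (inherits(x, "jsd_balance")) x else fit_jsd_table(x)
  tibble::tibble(level = names(fit$level_totals), bits = unname(fit$level_totals))
}

#' Rank cells by their absolute contribution to the JSD
#'
#' Sorts the cell decomposition by `abs(bits)`, descending, to surface the
#' treatment-group / covariate-level combinations most responsible for the
#' observed imbalance. Ties are broken by covariate-level order, then
#' group order, so the listing is deterministic.
#'
#' @inheritParams group_profiles
#' @return The [decompose_jsd()] tibble with an extra `abs_bits` column,
#'   sorted by `abs_bits` descending.
#' @export
rank_contributions <- function(x) {
  fit <- if (inherits(x, "jsd_balance")) x else fit_jsd_table(x)
  cells <- decompose_jsd(fit)
  cells$abs_bits <- abs(cells$bits)
  lev_ord <- match(cells$level, rownames(fit$cell))
  grp_ord <- match(cells$group, colnames(fit$cell))
  cells[order(-cells$abs_bits, lev_ord, grp_ord), , drop = FALSE]
}

#' @describeIn jsd_balance Long tibble of cell contributions (one row per
#'   level x group cell); identical to [decompose_jsd()].
#' @param x A `jsd_balance` fit.
#' @param ... Unused; for generic consistency.
#' @export
tidy.jsd_balance <- function(x, ...) {
  decompose_jsd(x)
}

#' @describeIn jsd_balance One-row model summary: `jsd_bits`,
#'   `max_jsd_bits`, `normalized_jsd`, `n_levels`, `n_groups`,
#'   `n_subjects`.
#' @export
glance.jsd_balance <- function(x, ...) {
  tibble::tibble(
    jsd_bits = x$jsd_bits,
    max_jsd_bits = x$max_jsd_bits,
    normalized_jsd = x$normalized_jsd,
    n_levels = nrow(x$table),
    n_groups = ncol(x$table),
    n_subjects = x$n_subjects
  )
}

#' @export
print.jsd_balance <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}
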