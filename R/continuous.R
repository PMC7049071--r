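#' Bin continuous covariate values into a balance table
#'
#' Discretizes a continuous covariate histogram-style so that the JSD
#' balance machinery applies: bin edges are computed once from the pooled
#' data across all groups (so every group shares the same bins), each
#' observation is assigned to exactly one bin, and per-group bin
#' occupancies become the counts of a [balance_table()]. Intervals are
#' left-closed/right-open, with the final interval closed on the right so
#' the pooled maximum is included.
#'
#' Binning trades resolution for estimability: with few bins, subtle
#' shape differences between groups can be masked, while many bins on a
#' small sample give noisy per-bin proportions. Refining an equal-width
#' partition can only increase (never decrease) the resulting JSD.
#'
#' @param data Data frame with one row per subject.
#' @param group,value Unquoted columns: the treatment-group label and the
#'   numeric covariate value. All values must be finite.
#' @param n_bins Number of bins (at least 2); default 10.
#' @param strategy `"equal_width"` (default) partitions the pooled range
#'   into equal-width intervals; `"quantile"` uses pooled-sample quantiles
#'   as edges. Duplicate quantile edges (heavily tied data) are collapsed
#'   with a warning, so fewer than `n_bins` bins may result.
#' @return A [balance_table()] of per-group bin counts, bins in order.
#' @examples
#' df <- data.frame(
#'   g = rep(c("A", "B"), each = 100),
#'   x = c(rnorm(100, 0, 1), rnorm(100, 0, 3))
#' )
#' bin_groups(df, g, x, n_bins = 8)
#' @export
bin_groups <- function(data, group, value, n_bins = 10,
                       strategy = c("equal_width", "quantile")) {
  strategy <- match.arg(strategy)
  g <- as.character(eval_tidy(enquo(group), data))
  v <- eval_tidy(enquo(value), data)
  if (!is.numeric(v)) abort_validation("`value` must be numeric.")
  if (anyNA(v) || any(!is.finite(v))) {
    abort_validation("`value` contains missing or non-finite observations.")
  }
  if (anyNA(g)) abort_validation("Missing treatment-group labels are not allowed.")
  grp <- unique(g)
  if (length(grp) < 2L) abort_validation("Binning requires at least 2 groups.")
  if (any(tabulate(factor(g, grp)) == 0L)) abort_validation("Every group must be non-empty.")
  if (length(n_bins) != 1L || n_bins < 2 || n_bins != round(n_bins)) {
    abort_validation("`n_bins` must be a single integer >= 2.")
  }
  edges <- bin_edges(v, n_bins, strategy)
  bins <- cut(v, breaks = edges, right = FALSE, include.lowest = TRUE, dig.lab = 6)
  m <- table(bins, factor(g, levels = grp))
  counts <- matrix(as.integer(m), nrow = nrow(m),
    dimnames = list(rownames(m), colnames(m))
  )
  balance_table(counts)
}

bin_edges <- function(v, n_bins, strategy) {
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) {
    abort_validation("Cannot bin a covariate with zero pooled range.")
  }
  if (strategy == "equal_width") {
    seq(lo, hi, length.out = n_bins + 1)
  } else {
    q <- quantile(v, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE, type = 7)
    edges <- unique(q)
    if (length(edges) < length(q)) {
      warn(sprintf(
        "Collapsed %d duplicate quantile edge(s); using %d bin(s).",
        length(q) - length(edges), length(edges) - 1
      ))
    }
    if (length(edges) < 3L) abort_validation("Quantile binning yields fewer than 2 bins.")
    edges
  }
}

#' Standardized difference score between two samples
#'
#' The difference in sample means divided by a combined standard
#' deviation, \eqn{(\bar x_1 - \bar x_2) / \sqrt{(s_1^2 + s_2^2)/2}},
#' using `(n - 1)` sample variances. Unlike the JSD, the score depends on
#' the first two moments only: two samples with equal means but different
#' spread, skewness, or modality score zero.
#'
#' @param x1,x2 Numeric samples, each with at least 2 observations.
#' @return The (signed, unitless) standardized difference.
#' @examples
#' standardized_difference(c(0, 2), c(1, 3)) # -1/sqrt(2)
#' @seealso [gaussian_sdiff()] for the population analogue.
#' @export
standardized_difference <- function(x1, x2) {
  for (x in list(x1, x2)) {
    if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(!is.finite(x))) {
      abort_validation("Each sample must hold >= 2 finite numeric observations.")
    }
  }
  s <- sqrt((var(x1) + var(x2)) / 2)
  if (s == 0) abort_domain("Combined standard deviation is zero; score undefined.")
  (mean(x1) - mean(x2)) / s
}

#' Population standardized difference of two Gaussians
#'
#' \eqn{(\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}}: the
#' population analogue of [standardized_difference()], used to
#' parameterize divergence curves.
#'
#' @param mu1,sigma1,mu2,sigma2 Means and standard deviations of the two
#'   Gaussian covariate distributions; `sigma1`, `sigma2` must be positive.
#' @return The (signed, unitless) standardized difference.
#' @examples
#' gaussian_sdiff(0, 1, 1, 3) # 1 unit apart, combined SD sqrt(5)
#' @export
gaussian_sdiff <- function(mu1, sigma1, mu2, sigma2) {
  check_gaussian(mu1, sigma1)
  check_gaussian(mu2, sigma2)
  (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)
}

check_gaussian <- function(mu, sigma) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
    abort_validation("A Gaussian spec needs a finite mean and a positive SD.")
  }
}

#' JSD between two Gaussian distributions, by quadrature
#'
#' Computes the Jensen-Shannon divergence between two normal densities,
#' \deqn{\tfrac12 \int f_1 \log_2 \frac{f_1}{\tilde f}
#'   + \tfrac12 \int f_2 \log_2 \frac{f_2}{\tilde f}, \qquad
#'   \tilde f = (f_1 + f_2)/2,}
#' by deterministic trapezoid-rule quadrature on an equally spaced grid
#' spanning `[min(mu) - 8 max(sigma), max(mu) + 8 max(sigma)]`. The
#' integrand is smooth, bounded, and decays with the Gaussian tails, so
#' the default 20,001-point grid resolves the integral well below `1e-6`
#' absolute error. The result lies in `[0, 1]` bits (two distributions)
#' and is zero only when the two specs coincide.
#'
#' @inheritParams gaussian_sdiff
#' @param n_grid Number of quadrature nodes (default 20,001).
#' @return The JSD in bits.
#' @examples
#' gaussian_jsd(0, 1, 0, 1) # 0: identical
#' gaussian_jsd(0, 1, 0, 3) # > 0 despite equal means
#' gaussian_jsd(0, 1, 20, 1) # ~1 bit: essentially disjoint
#' @export
gaussian_jsd <- function(mu1, sigma1, mu2, sigma2, n_grid = 20001) {
  check_gaussian(mu1, sigma1)
  check_gaussian(mu2, sigma2)
  if (length(n_grid) != 1L || n_grid < 101) {
    abort_validation("`n_grid` must be a single integer >= 101.")
  }
  lo <- min(mu1, mu2) - 8 * max(sigma1, sigma2)
  hi <- max(mu1, mu2) + 8 * max(sigma1, sigma2)
  x <- seq(lo, hi, length.out = n_grid)
  f1 <- dnorm(x, mu1, sigma1)
  f2 <- dnorm(x, mu2, sigma2)
  mix <- (f1 + f2) / 2
  integrand <- 0.5 * (xlogx_ratio(f1, mix) + xlogx_ratio(f2, mix))
  h <- (hi - lo) / (n_grid - 1)
  val <- h * (sum(integrand) - 0.5 * (integrand[1] + integrand[n_grid]))
  min(max(val, 0), 1)
}

#' JSD as a function of the standardized difference score
#'
#' Traces how the JSD between two Gaussian covariate distributions grows
#' with their standardized difference, for a fixed ratio of standard
#' deviations. The first group is fixed at `Normal(0, 1)`; for each target
#' standardized difference `d` the second group is `Normal(mu2, sigma2)`
#' with `mu2 = -d * sqrt((1 + sigma2^2) / 2)`, so that
#' [gaussian_sdiff()] of the pair equals `d` exactly.
#'
#' Two contrasts with the standardized difference score are visible in
#' the curves: the JSD saturates at 1 bit as the groups separate (the
#' score is unbounded), and with `sigma2 != 1` the JSD is strictly
#' positive at `d = 0` (the score is blind to a pure spread difference).
#'
#' @param sigma2 Standard deviation of the second group (first group has
#'   SD 1).
#' @param sdiff_grid Sorted vector of target standardized differences.
#' @inheritParams gaussian_jsd
#' @return A tibble of class `"divergence_curve"` with columns
#'   `standardized_difference` and `jsd_bits`, and attribute `sigma2`.
#' @examples
#' sdiff_jsd_curve(3, seq(0, 4, by = 0.5))
#' @export
sdiff_jsd_curve <- function(sigma2, sdiff_grid = seq(0, 4, length.out = 81),
                            n_grid = 20001) {
  check_gaussian(0, sigma2)
  if (!is.numeric(sdiff_grid) || length(sdiff_grid) < 1L ||
      anyNA(sdiff_grid) || any(!is.finite(sdiff_grid)) || is.unsorted(sdiff_grid)) {
    abort_validation("`sdiff_grid` must be a sorted vector of finite values.")
  }
  mu2 <- -sdiff_grid * sqrt((1 + sigma2^2) / 2)
  jsd <- vapply(mu2, function(m) gaussian_jsd(0, 1, m, sigma2, n_grid = n_grid), numeric(1))
  out <- tibble::tibble(standardized_difference = sdiff_grid, jsd_bits = jsd)
  attr(out, "sigma2") <- sigma2
  class(out) <- c("divergence_curve", class(out))
  out
}
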