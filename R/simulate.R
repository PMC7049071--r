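#' Simulate multinomial counts from per-group covariate distributions
#'
#' Draws each treatment group's covariate-level counts from a multinomial
#' distribution with the stated probabilities. As group sizes grow the JSD
#' of the simulated table converges to the JSD of the generating
#' distributions, which makes this the workhorse for calibration checks.
#'
#' @param probs Levels-by-groups matrix (or data frame with a leading
#'   level column) of per-group covariate probabilities; every column must
#'   sum to 1 within `1e-9`.
#' @param n_per_group Subjects per group; a single number or one per group.
#' @param seed Optional integer seed; when supplied the draw is fully
#'   reproducible (Mersenne-Twister, recorded in the `rng` attribute).
#' @return A [balance_table()] of simulated counts with attributes `seed`
#'   and `rng`.
#' @examples
#' p <- cbind(A = c(0.7, 0.2, 0.1), B = c(0.5, 0.3, 0.2))
#' simulate_multinomial_counts(p, n_per_group = 1000, seed = 1)
#' @export
simulate_multinomial_counts <- function(probs, n_per_group, seed = NULL) {
  if (is.data.frame(probs)) {
    lev <- as.character(probs[[1]])
    probs <- as.matrix(probs[-1])
    rownames(probs) <- lev
  }
  if (!is.matrix(probs) || !is.numeric(probs) || ncol(probs) < 2L) {
    abort_validation("`probs` must be a numeric matrix with >= 2 group columns.")
  }
  for (k in seq_len(ncol(probs))) check_probs(probs[, k], arg = sprintf("probs[, %d]", k))
  n_groups <- ncol(probs)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, n_groups)
  if (length(n_per_group) != n_groups || any(n_per_group < 1) ||
      any(n_per_group != round(n_per_group))) {
    abort_validation("`n_per_group` must be positive integers, one (or one each) per group.")
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(
    seq_len(n_groups),
    function(k) as.integer(rmultinom(1, size = n_per_group[k], prob = probs[, k])),
    integer(nrow(probs))
  )
  dimnames(counts) <- list(
    rownames(probs) %||% paste0("level_", seq_len(nrow(probs))),
    colnames(probs) %||% paste0("group_", seq_len(n_groups))
  )
  out <- balance_table(counts)
  attr(out, "seed") <- seed
  attr(out, "rng") <- RNGkind()[1]
  out
}

# Named two-group Gaussian-mixture scenarios. Except for the plain
# location shift, each pair has identical means (standardized difference
# ~ 0) yet visibly different shape -- the regime where the JSD detects
# imbalance that the standardized difference score cannot.
mixture_presets <- function(preset) {
  sd_bimodal <- sqrt(0.5 * (4 + 0.49) + 0.5 * (4 + 0.49) - 0) # var of 0.5N(-2,.7)+0.5N(2,.7)
  presets <- list(
    "location-shift" = list(
      A = list(weights = 1, means = 0, sds = 1),
      B = list(weights = 1, means = 1, sds = 1)
    ),
    "scale-difference" = list(
      A = list(weights = 1, means = 0, sds = 1),
      B = list(weights = 1, means = 0, sds = 3)
    ),
    "skew-mirror" = list(
      A = list(weights = c(0.75, 0.25), means = c(-0.5, 1.5), sds = c(0.6, 1.0)),
      B = list(weights = c(0.75, 0.25), means = c(0.5, -1.5), sds = c(0.6, 1.0))
    ),
    "bimodal-vs-unimodal" = list(
      A = list(weights = 1, means = 0, sds = sd_bimodal),
      B = list(weights = c(0.5, 0.5), means = c(-2, 2), sds = c(0.7, 0.7))
    )
  )
  if (!preset %in% names(presets)) {
    abort_validation(sprintf(
      "Unknown preset '%s'; available: %s.",
      preset, paste(names(presets), collapse = ", ")
    ))
  }
  presets[[preset]]
}

#' Simulate continuous covariate samples from Gaussian-mixture groups
#'
#' Generates subject-level records for two or more treatment groups whose
#' covariate follows a per-group Gaussian mixture. Named presets cover the
#' canonical shape scenarios for contrasting the JSD with the
#' standardized difference score: `"location-shift"` (the one case the
#' score detects), and three matched-mean pairs the score cannot detect —
#' `"scale-difference"`, `"skew-mirror"`, and `"bimodal-vs-unimodal"`.
#'
#' @param n_per_group Subjects per group.
#' @param preset Name of a built-in two-group scenario (see above);
#'   ignored when `spec` is supplied.
#' @param spec Optional custom specification: a named list (one entry per
#'   group) of lists with `weights`, `means`, `sds` of equal length;
#'   weights positive, summing to 1.
#' @param seed Optional integer seed for reproducibility.
#' @return A `"long_records"` tibble (`group`, `covariate`) with
#'   attributes `kind = "continuous"`, `seed`, and `rng`; ready for
#'   [tabulate_records()] or [bin_groups()].
#' @examples
#' recs <- simulate_gaussian_groups(500, preset = "scale-difference", seed = 7)
#' jsd_balance(tabulate_records(recs, n_bins = 10))$jsd_bits
#' @export
simulate_gaussian_groups <- function(n_per_group, preset = "scale-difference",
                                     spec = NULL, seed = NULL) {
  spec <- spec %||% mixture_presets(preset)
  if (!is.list(spec) || length(spec) < 2L || is.null(names(spec))) {
    abort_validation("`spec` must be a named list with >= 2 groups.")
  }
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (!all(c("weights", "means", "sds") %in% names(s)) ||
        length(unique(lengths(s[c("weights", "means", "sds")]))) != 1L) {
      abort_validation(sprintf("Group '%s': needs equal-length weights/means/sds.", nm))
    }
    if (any(s$weights <= 0) || abs(sum(s$weights) - 1) > 1e-9) {
      abort_validation(sprintf("Group '%s': weights must be positive and sum to 1.", nm))
    }
    if (any(s$sds <= 0)) abort_validation(sprintf("Group '%s': sds must be positive.", nm))
  }
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, length(spec))
  if (length(n_per_group) != length(spec) || any(n_per_group < 1)) {
    abort_validation("`n_per_group` must be positive, one (or one each) per group.")
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- purrr::map2(spec, n_per_group, function(s, n) {
    comp <- sample.int(length(s$weights), size = n, replace = TRUE, prob = s$weights)
    rnorm(n, mean = s$means[comp], sd = s$sds[comp])
  })
  out <- tibble::tibble(
    group = rep(names(spec), times = n_per_group),
    covariate = unlist(samples, use.names = FALSE)
  )
  attr(out, "kind") <- "continuous"
  attr(out, "seed") <- seed
  attr(out, "rng") <- RNGkind()[1]
  class(out) <- c("long_records", class(out))
  out
}
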