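#' Shannon entropy of a discrete distribution
#'
#' Computes \eqn{H(X) = -\sum_i p_i \log_2 p_i}, the expected number of bits
#' needed to encode outcomes of a discrete random variable under an optimal
#' code. Zero-probability categories contribute nothing (the
#' \eqn{0 \log 0 = 0} continuity convention).
#'
#' @param p Numeric vector of probabilities, optionally named by category.
#'   Must be non-negative and sum to 1 within `1e-9`.
#' @param base Base of the logarithm. The default `2` gives bits, the unit
#'   used throughout the package's balance reports; `exp(1)` gives nats.
#'
#' @return The entropy, a single number in `[0, log2(M)]` for an
#'   `M`-category distribution (when `base = 2`).
#'
#' @examples
#' entropy(c(A = 0.25, B = 0.125, C = 0.5, D = 0.125)) # 1.75 bits
#' entropy(c(2 / 3, 1 / 3)) # 0.9183 bits
#' @seealso [relative_entropy()], [jsd_divergence()]
#' @export
entropy <- function(p, base = 2) {
  p <- check_probs(p)
  pos <- p > 0
  -sum(p[pos] * log(p[pos], base = base))
}

#' Joint entropy of a two-way distribution
#'
#' Entropy of the flattened joint distribution \eqn{H(X, Y)}: the lower
#' limit on the average number of bits needed to encode a pair of outcomes.
#'
#' @param joint Numeric matrix of joint probabilities `f(x_i, y_j)`, rows
#'   indexing `X` and columns indexing `Y`; non-negative, summing to 1.
#' @inheritParams entropy
#' @return The joint entropy in the units set by `base`.
#' @examples
#' joint_entropy(outer(c(0.5, 0.5), c(0.5, 0.5))) # 2 bits
#' @export
joint_entropy <- function(joint, base = 2) {
  joint <- check_joint(joint)
  entropy(as.vector(joint), base = base)
}

#' Conditional entropy H(X | Y)
#'
#' Residual uncertainty in one variable after observing the other, computed
#' from the joint table as \eqn{-\sum_{ij} f(x_i, y_j) \log_2 f(x_i | y_j)}.
#' It equals `joint_entropy(joint) - entropy(marginal of the conditioning
#' variable)`; cells in zero-probability slices are skipped.
#'
#' @inheritParams joint_entropy
#' @param given Which margin is observed: `"cols"` (the default; condition
#'   on `Y`, returning `H(X | Y)`) or `"rows"` (condition on `X`, returning
#'   `H(Y | X)`).
#' @return The conditional entropy in the units set by `base`.
#' @examples
#' j <- matrix(c(0.5, 0, 0, 0.5), 2) # Y determines X
#' conditional_entropy(j) # 0 bits
#' @export
conditional_entropy <- function(joint, given = c("cols", "rows"), base = 2) {
  joint <- check_joint(joint)
  given <- match.arg(given)
  if (given == "rows") joint <- t(joint)
  marg <- colSums(joint)
  keep <- marg > 0
  cond <- sweep(joint[, keep, drop = FALSE], 2, marg[keep], "/")
  jk <- joint[, keep, drop = FALSE]
  pos <- jk > 0
  -sum(jk[pos] * log(cond[pos], base = base))
}

#' Mutual information I(X; Y)
#'
#' The expected amount of information that observing one variable provides
#' about the other: \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)}. Symmetric in the
#' two variables and non-negative; zero exactly when the joint table is the
#' outer product of its margins (independence).
#'
#' @inheritParams joint_entropy
#' @return The mutual information in the units set by `base`.
#' @examples
#' mutual_information(outer(c(0.3, 0.7), c(0.5, 0.5))) # 0: independent
#' @export
mutual_information <- function(joint, base = 2) {
  joint <- check_joint(joint)
  hx <- entropy(rowSums(joint), base = base)
  hy <- entropy(colSums(joint), base = base)
  max(hx + hy - joint_entropy(joint, base = base), 0)
}

#' Relative entropy (Kullback-Leibler divergence)
#'
#' Computes \eqn{D(g \| f) = \sum_i g_i \log_2 (g_i / f_i)}: the expected
#' extra bits needed to encode draws from `g` using a code optimized for
#' `f`. Non-negative, zero iff `g = f`, and asymmetric in its arguments —
#' which is why the balance statistic uses the Jensen-Shannon divergence
#' ([jsd_divergence()]) rather than relative entropy directly.
#'
#' The divergence is infinite when `g` puts mass on a category where `f`
#' has none; rather than return `Inf`, this raises a domain error naming
#' the offending label, since an infinite divergence signals an undefined
#' balance comparison.
#'
#' @param g Target distribution (the expectation is taken under `g`).
#' @param f Reference distribution, on the same label set as `g`. Named
#'   vectors are aligned by label; unnamed vectors positionally.
#' @inheritParams entropy
#' @return The divergence from `f` to `g`, in the units set by `base`.
#' @examples
#' relative_entropy(c(0.5, 0.5), c(0.25, 0.75))
#' relative_entropy(c(0.25, 0.75), c(0.5, 0.5)) # different: asymmetric
#' @export
relative_entropy <- function(g, f, base = 2) {
  g <- check_probs(g, arg = "g")
  f <- check_probs(f, arg = "f")
  pair <- align_pair(g, f)
  g <- pair$g
  f <- pair$f
  bad <- g > 0 & f == 0
  if (any(bad)) {
    lab <- if (!is.null(names(g))) names(g)[bad][1] else paste0("#", which(bad)[1])
    abort_domain(sprintf(
      "Relative entropy is infinite: `g` has mass at category %s where `f` has none.", lab
    ))
  }
  sum(xlogx_ratio(g, f, log_base = base))
}

#' Jeffreys divergence
#'
#' The symmetrized sum of the two directed relative entropies,
#' \eqn{J(g; f) = D(g \| f) + D(f \| g)}. Symmetric and non-negative, but
#' defined only for pairs of distributions (and infinite when either
#' support is not contained in the other), which limits its use as a
#' multi-group balance measure.
#'
#' @inheritParams relative_entropy
#' @return The Jeffreys divergence in the units set by `base`.
#' @examples
#' jeffreys_divergence(c(0.5, 0.5), c(0.25, 0.75))
#' @export
jeffreys_divergence <- function(g, f, base = 2) {
  relative_entropy(g, f, base = base) + relative_entropy(f, g, base = base)
}

#' Jensen-Shannon divergence of N discrete distributions
#'
#' Forms the mixture \eqn{\tilde f = \sum_k w_k f_k} and returns
#' \eqn{\mathrm{JSD} = \sum_k w_k D(f_k \| \tilde f)}. With the default
#' uniform weights this is the average relative entropy from the unweighted
#' mean of the distributions to each component — the quantity used as the
#' covariate-balance statistic. It is always finite (the mixture support
#' covers every component's support), zero iff all distributions are
#' identical, and at most `log2(N)` bits for uniform weights.
#'
#' @param dists A list of probability vectors on a common label set, or a
#'   numeric matrix with one column per distribution.
#' @param weights Optional positive mixture weights summing to 1. The
#'   default `NULL` uses uniform weights `1/N`, the convention under which
#'   balance statistics are reported; non-uniform weights are an extension.
#' @inheritParams entropy
#' @return The Jensen-Shannon divergence in the units set by `base`.
#' @examples
#' jsd_divergence(list(c(0.5, 0.5), c(0.5, 0.5))) # 0: identical
#' jsd_divergence(diag(3)) # log2(3) = 1.585: disjoint point masses
#' @seealso [jsd_balance()] for the table-based balance workflow.
#' @export
jsd_divergence <- function(dists, weights = NULL, base = 2) {
  if (is.matrix(dists)) {
    dists <- lapply(seq_len(ncol(dists)), function(k) {
      v <- dists[, k]
      names(v) <- rownames(dists)
      v
    })
  }
  if (!is.list(dists) || length(dists) < 2L) {
    abort_validation("`dists` must supply at least 2 distributions.")
  }
  n <- length(dists)
  dists <- lapply(seq_len(n), function(k) check_probs(dists[[k]], arg = sprintf("dists[[%d]]", k)))
  labs <- names(dists[[1]])
  if (!is.null(labs)) {
    dists <- lapply(dists, function(d) {
      if (is.null(names(d)) || !setequal(names(d), labs)) {
        abort_validation("All distributions must share one label set.")
      }
      d[labs]
    })
  } else if (length(unique(lengths(dists))) != 1L) {
    abort_validation("All distributions must have the same number of categories.")
  }
  if (is.null(weights)) {
    weights <- rep(1 / n, n)
  } else {
    if (length(weights) != n || any(weights <= 0)) {
      abort_validation("`weights` must be positive, one per distribution.")
    }
    if (abs(sum(weights) - 1) > 1e-9) {
      abort_validation("`weights` must sum to 1.")
    }
  }
  mat <- do.call(cbind, dists)
  mixture <- as.vector(mat %*% weights)
  sum(vapply(
    seq_len(n),
    function(k) weights[k] * sum(xlogx_ratio(mat[, k], mixture, log_base = base)),
    numeric(1)
  ))
}

#' Expected length of a prefix code
#'
#' Average number of bits per outcome transmitted under a prefix code:
#' \eqn{\sum_i p_i \ell_i}, divided by `outcomes_per_codeword` when each
#' codeword encodes a block of outcomes. Code lengths must satisfy the
#' Kraft inequality \eqn{\sum_i 2^{-\ell_i} \le 1}, the condition for a
#' decodable prefix code; Shannon's bound guarantees the result is never
#' below the entropy of the source per outcome.
#'
#' @param p Probabilities of the encoded symbols (for a block code, of the
#'   blocks). Named vectors are matched to `code_lengths` by label.
#' @param code_lengths Positive integer codeword lengths in bits, one per
#'   symbol of `p`.
#' @param outcomes_per_codeword Number of source outcomes each codeword
#'   encodes (block length); the default 1 codes single outcomes.
#' @return Expected code length in bits per outcome.
#' @examples
#' # optimal code for {0.25, 0.125, 0.5, 0.125} reaches the entropy, 1.75 bits
#' expected_code_length(
#'   c(A = 0.25, B = 0.125, C = 0.5, D = 0.125),
#'   c(A = 2, B = 3, C = 1, D = 3)
#' )
#' @export
expected_code_length <- function(p, code_lengths, outcomes_per_codeword = 1) {
  p <- check_probs(p)
  if (!is.numeric(code_lengths) || length(code_lengths) != length(p) ||
      any(code_lengths <= 0) || any(code_lengths != round(code_lengths))) {
    abort_validation("`code_lengths` must be positive integers, one per category of `p`.")
  }
  if (!is.null(names(p)) && !is.null(names(code_lengths))) {
    if (!setequal(names(p), names(code_lengths))) {
      abort_validation("`p` and `code_lengths` are labeled over different symbols.")
    }
    code_lengths <- code_lengths[names(p)]
  }
  if (sum(2^(-code_lengths)) > 1 + 1e-12) {
    abort_validation("`code_lengths` violate the Kraft inequality: no prefix code exists.")
  }
  if (length(outcomes_per_codeword) != 1L || outcomes_per_codeword < 1) {
    abort_validation("`outcomes_per_codeword` must be a positive integer.")
  }
  sum(p * code_lengths) / outcomes_per_codeword
}

#' Maximum attainable Jensen-Shannon divergence
#'
#' The JSD of `n_groups` distributions with uniform weights is bounded by
#' `log2(n_groups)` bits, attained exactly when the groups have disjoint
#' covariate support. Reported alongside the observed statistic to give it
#' scale.
#'
#' @param n_groups Number of treatment groups (at least 2).
#' @return `log2(n_groups)` bits.
#' @examples
#' max_jsd(3) # 1.585 bits
#' max_jsd(2) # 1 bit
#' @export
max_jsd <- function(n_groups) {
  if (length(n_groups) != 1L || !is.finite(n_groups) || n_groups < 2 ||
      n_groups != round(n_groups)) {
    abort_validation("`n_groups` must be a single integer >= 2.")
  }
  log2(n_groups)
}
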