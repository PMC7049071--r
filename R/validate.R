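# Internal condition helpers. Validation errors flag malformed inputs
# (bad probabilities, bad tables, bad files); domain errors flag inputs that
# are well-formed but for which the requested quantity is undefined
# (infinite divergence, zero combined SD). The CLI maps both to exit 1.

abort_validation <- function(message, ...) {
  abort(message, class = c("jsdbalance_validation_error", "jsdbalance_error"), ...)
}

abort_domain <- function(message, ...) {
  abort(message, class = c("jsdbalance_domain_error", "jsdbalance_error"), ...)
}

# Probability vectors are plain numeric vectors, optionally named.
# Construction from counts divides by the exact total, so sums are exact;
# user-supplied probabilities must sum to 1 within `tol`.
check_probs <- function(p, tol = 1e-9, arg = "p") {
  if (!is.numeric(p) || length(p) < 1L) {
    abort_validation(sprintf("`%s` must be a non-empty numeric vector of probabilities.", arg))
  }
  if (anyNA(p) || any(!is.finite(p))) {
    abort_validation(sprintf("`%s` contains missing or non-finite probabilities.", arg))
  }
  if (any(p < 0)) {
    abort_validation(sprintf("`%s` contains negative probabilities.", arg))
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    abort_validation(sprintf("`%s` must sum to 1 (got %.12g).", arg, s))
  }
  nm <- names(p)
  if (!is.null(nm) && anyDuplicated(nm)) {
    abort_validation(sprintf("`%s` has duplicated category labels.", arg))
  }
  p
}

check_joint <- function(j, tol = 1e-9) {
  if (!is.matrix(j) || !is.numeric(j)) {
    abort_validation("A joint distribution must be a numeric matrix.")
  }
  if (anyNA(j) || any(!is.finite(j)) || any(j < 0)) {
    abort_validation("Joint probabilities must be finite and non-negative.")
  }
  if (abs(sum(j) - 1) > tol) {
    abort_validation(sprintf("Joint probabilities must sum to 1 (got %.12g).", sum(j)))
  }
  j
}

# Align two distributions on a common label set. Unnamed vectors of equal
# length are matched positionally.
align_pair <- function(g, f) {
  if (!is.null(names(g)) && !is.null(names(f))) {
    if (!setequal(names(g), names(f))) {
      abort_validation("`g` and `f` are defined over different label sets.")
    }
    f <- f[names(g)]
  } else if (length(g) != length(f)) {
    abort_validation("`g` and `f` must have the same number of categories.")
  }
  list(g = g, f = f)
}

# x * log(x / y) with the 0 * log(0) = 0 continuity convention: terms with
# zero mass in the outer (expectation-taking) distribution contribute nothing.
xlogx_ratio <- function(x, y, log_base = 2) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / y[pos], base = log_base)
  out
}
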