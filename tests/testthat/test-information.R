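test_that("entropy matches worked coding examples and closed forms", {
  expect_equal(entropy(c(A = 0.25, B = 0.125, C = 0.5, D = 0.125)), 1.75)
  expect_equal(round(entropy(c(2 / 3, 1 / 3)), 4), 0.9183)
  expect_equal(entropy(c(A = 1)), 0)
  expect_equal(entropy(rep(1 / 8, 8)), 3)
  expect_equal(entropy(c(0.5, 0.5), base = exp(1)), log(2))
})

test_that("entropy rejects invalid distributions", {
  expect_error(entropy(c(0.5, 0.6)), class = "jsdbalance_validation_error")
  expect_error(entropy(c(-0.1, 1.1)), class = "jsdbalance_validation_error")
  expect_error(entropy(c(A = 0.5, A = 0.5)), class = "jsdbalance_validation_error")
})

test_that("entropy stays within [0, log2(M)] on random distributions", {
  set.seed(11)
  for (i in 1:100) {
    m <- sample(2:10, 1)
    h <- entropy(random_probs(m))
    expect_gte(h, 0)
    expect_lte(h, log2(m) + 1e-12)
  }
})

test_that("joint entropy handles independence, coupling, and degenerate margins", {
  expect_equal(joint_entropy(outer(c(0.5, 0.5), c(0.5, 0.5))), 2)
  expect_equal(joint_entropy(matrix(c(0.5, 0, 0, 0.5), 2)), 1)
  # when Y is a point mass the joint entropy is the marginal entropy of X
  j <- outer(c(0.25, 0.125, 0.5, 0.125), c(1, 0))
  expect_equal(joint_entropy(j), 1.75)
})

test_that("conditional entropy obeys the chain rule and determinism cases", {
  indep <- outer(c(0.3, 0.7), c(0.4, 0.6))
  expect_equal(conditional_entropy(indep), entropy(c(0.3, 0.7)))
  expect_equal(conditional_entropy(matrix(c(0.5, 0, 0, 0.5), 2)), 0)
  j <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  expect_equal(conditional_entropy(j), joint_entropy(j) - entropy(colSums(j)),
    tolerance = 1e-12
  )
  set.seed(21)
  for (i in 1:100) {
    j <- random_joint(sample(2:6, 1), sample(2:6, 1))
    expect_equal(
      conditional_entropy(j) + entropy(colSums(j)),
      joint_entropy(j),
      tolerance = 1e-12
    )
    expect_equal(conditional_entropy(j, given = "rows"),
      joint_entropy(j) - entropy(rowSums(j)),
      tolerance = 1e-12
    )
  }
})

test_that("mutual information is symmetric, non-negative, zero under independence", {
  expect_equal(mutual_information(outer(c(0.3, 0.7), c(0.4, 0.6))), 0, tolerance = 1e-12)
  expect_equal(mutual_information(matrix(c(0.5, 0, 0, 0.5), 2)), 1)
  set.seed(31)
  for (i in 1:100) {
    j <- random_joint(3, 3)
    expect_equal(mutual_information(j), mutual_information(t(j)), tolerance = 1e-12)
    expect_gte(mutual_information(j), 0)
    expect_equal(
      mutual_information(j),
      entropy(rowSums(j)) - conditional_entropy(j),
      tolerance = 1e-12
    )
  }
})

test_that("relative entropy matches direct summation and is asymmetric", {
  g <- c(0.5, 0.5)
  f <- c(0.25, 0.75)
  # oracle: explicit two-term sums
  d_gf <- 0.5 * log2(0.5 / 0.25) + 0.5 * log2(0.5 / 0.75)
  d_fg <- 0.25 * log2(0.25 / 0.5) + 0.75 * log2(0.75 / 0.5)
  expect_equal(relative_entropy(g, f), d_gf, tolerance = 1e-15)
  expect_equal(relative_entropy(f, g), d_fg, tolerance = 1e-15)
  expect_false(isTRUE(all.equal(relative_entropy(g, f), relative_entropy(f, g))))
  expect_equal(relative_entropy(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(relative_entropy(g, g), 0)
})

test_that("relative entropy is non-negative and zero iff equal (Gibbs)", {
  set.seed(41)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    g <- random_probs(m)
    f <- random_probs(m)
    expect_gte(relative_entropy(g, f), 0)
    expect_equal(relative_entropy(g, g), 0)
  }
})

test_that("relative entropy fails loudly on infinite divergence and label mismatch", {
  expect_error(
    relative_entropy(c(A = 0.5, B = 0.5), c(A = 1, B = 0)),
    regexp = "B",
    class = "jsdbalance_domain_error"
  )
  expect_error(
    relative_entropy(c(A = 0.5, B = 0.5), c(A = 0.5, C = 0.5)),
    class = "jsdbalance_validation_error"
  )
})

test_that("Jeffreys divergence is the symmetric sum of directed divergences", {
  g <- c(0.5, 0.5)
  f <- c(0.25, 0.75)
  expect_equal(
    jeffreys_divergence(g, f),
    relative_entropy(g, f) + relative_entropy(f, g),
    tolerance = 1e-15
  )
  expect_equal(jeffreys_divergence(g, g), 0)
  set.seed(51)
  for (i in 1:50) {
    a <- random_probs(4)
    b <- random_probs(4)
    expect_equal(jeffreys_divergence(a, b), jeffreys_divergence(b, a), tolerance = 1e-12)
  }
})

test_that("JSD of distributions hits its known values", {
  expect_equal(jsd_divergence(list(c(0.2, 0.8), c(0.2, 0.8), c(0.2, 0.8))), 0)
  expect_equal(round(jsd_divergence(diag(3)), 4), 1.5850)
  expect_equal(jsd_divergence(diag(3)), log2(3), tolerance = 1e-12)
  tab <- glucose_counts()
  profs <- sweep(unclass(tab), 2, colSums(tab), "/")
  expect_equal(round(jsd_divergence(profs), 4), 0.0144)
})

test_that("JSD validates its inputs and supports explicit weights", {
  expect_error(jsd_divergence(list(c(0.5, 0.5))), class = "jsdbalance_validation_error")
  expect_error(
    jsd_divergence(list(c(A = 1), c(B = 1))),
    class = "jsdbalance_validation_error"
  )
  expect_error(
    jsd_divergence(list(c(0.5, 0.5), c(0.5, 0.5)), weights = c(0.9, 0.2)),
    class = "jsdbalance_validation_error"
  )
  # uniform weights are the default; supplying them explicitly changes nothing
  a <- c(0.1, 0.9)
  b <- c(0.6, 0.4)
  expect_equal(
    jsd_divergence(list(a, b)),
    jsd_divergence(list(a, b), weights = c(0.5, 0.5))
  )
})

test_that("JSD agrees with the mixture-entropy identity and is permutation invariant", {
  set.seed(61)
  for (i in 1:100) {
    m <- sample(2:7, 1)
    n <- sample(2:5, 1)
    dists <- replicate(n, random_probs(m), simplify = FALSE)
    jsd <- jsd_divergence(dists)
    # independent oracle: H(mixture) - mean of component entropies
    mix <- Reduce(`+`, dists) / n
    expect_equal(jsd, entropy(mix) - mean(vapply(dists, entropy, numeric(1))),
      tolerance = 1e-12
    )
    expect_equal(jsd, jsd_divergence(dists[sample(n)]), tolerance = 1e-12)
    relab <- sample(m)
    expect_equal(jsd, jsd_divergence(lapply(dists, function(d) d[relab])),
      tolerance = 1e-12
    )
  }
})

test_that("expected code length reproduces the coding examples", {
  p <- c(A = 0.25, B = 0.125, C = 0.5, D = 0.125)
  len <- c(A = 2, B = 3, C = 1, D = 3)
  expect_equal(expected_code_length(p, len), 1.75)
  # block code on pairs from {2/3, 1/3}
  blocks <- c(AA = 4 / 9, AB = 2 / 9, BA = 2 / 9, BB = 1 / 9)
  expect_equal(
    round(expected_code_length(blocks, c(AA = 1, AB = 2, BA = 3, BB = 3),
      outcomes_per_codeword = 2
    ), 4),
    0.9444
  )
  expect_equal(expected_code_length(rep(0.25, 4), rep(2, 4)), 2)
  expect_error(
    expected_code_length(c(0.5, 0.5), c(1, 1, 1)),
    class = "jsdbalance_validation_error"
  )
  expect_error(
    expected_code_length(rep(0.25, 4), rep(1, 4)), # Kraft sum = 2
    class = "jsdbalance_validation_error"
  )
})

test_that("no Kraft-valid code beats the entropy (Shannon bound)", {
  set.seed(71)
  for (i in 1:100) {
    m <- sample(2:10, 1)
    p <- random_probs(m)
    lengths <- ceiling(-log2(p)) # Shannon code: always Kraft-valid
    expect_gte(expected_code_length(p, lengths), entropy(p) - 1e-12)
  }
})
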