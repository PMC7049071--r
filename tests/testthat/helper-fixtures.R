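# Fixtures are built in code so every test is self-contained.

glucose_counts <- function() {
  balance_table(matrix(
    c(7191, 1025, 1715, 3637, 835, 685, 64265, 7298, 6932),
    nrow = 3,
    dimnames = list(
      c("<109", "109-125", ">125"),
      c("Disadvantaged", "Elderly", "Reference")
    )
  ))
}

# Strictly positive cells so tables never trip the empty-level path.
random_table <- function(n_levels, n_groups) {
  balance_table(matrix(
    sample.int(60, n_levels * n_groups, replace = TRUE),
    nrow = n_levels,
    dimnames = list(paste0("L", seq_len(n_levels)), paste0("G", seq_len(n_groups)))
  ))
}

random_probs <- function(m) {
  x <- rgamma(m, shape = 1)
  x / sum(x)
}

random_joint <- function(m, n) {
  x <- matrix(rgamma(m * n, shape = 1), nrow = m)
  x / sum(x)
}
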