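# Independent oracles and shared fixtures for the test suite.

# Brute-force greedy mRMR oracle: recomputes relevance and redundancy from
# scratch each round with the public pairwise mutual_information(), entirely
# independent of the vectorized ranking internals.
brute_mrmr_oracle <- function(states, labels, top_n = ncol(states),
                              criterion = "difference") {
  p <- ncol(states)
  rel <- vapply(seq_len(p),
                function(j) mutual_information(states[, j], labels), 0)
  selected <- integer(0)
  for (round in seq_len(top_n)) {
    best <- -Inf
    best_j <- NA_integer_
    for (j in seq_len(p)) {
      if (j %in% selected) next
      if (!length(selected)) {
        score <- rel[j]
      } else {
        red <- mean(vapply(selected, function(s)
          mutual_information(states[, j], states[, s]), 0))
        score <- if (criterion == "difference") rel[j] - red
                 else if (red > 0) rel[j] / red else rel[j]
      }
      if (score > best) {           # strictly better; ties keep earlier j
        best <- score
        best_j <- j
      }
    }
    selected <- c(selected, best_j)
  }
  colnames(states)[selected]
}

# Hypergeometric upper-tail by explicit pmf enumeration with choose().
hyper_tail_enum <- function(a, b, c_, d) {
  K <- a + c_; n <- a + b; N <- a + b + c_ + d
  if (n == 0 || K == 0) return(1)
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Two-sample t statistics per probe, computed straight from the matrix.
probe_t_stats <- function(mat) {
  pos <- is_positive(mat)
  apply(mat$values, 2L, function(v)
    unname(stats::t.test(v[pos], v[!pos])$statistic))
}

# Small reusable synthetic cohort.
small_cohort <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(n_pos = 30L, n_neg = 20L, p_total = 200L, n_informative = 5L,
         seed = seed),
    list(...))
  generate_cna(do.call(synthetic_spec, args))
}

expect_same_ranking <- function(ranked, expected_ids) {
  expect_identical(ranked$probe_id, expected_ids)
}
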