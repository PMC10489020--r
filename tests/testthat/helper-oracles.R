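# Independent brute-force oracles, written before the package internals.
# Deliberately naive: explicit loops, one column at a time, no sharing of
# code with the fast paths they are used to check.

# n-ary Jaccard-Tanimoto via the printed coincidence rules, column by column
oracle_extended_jt <- function(bits, gamma) {
  n <- nrow(bits)
  sum_delta <- 0L
  n_one <- 0L
  n_dis <- 0L
  for (k in seq_len(ncol(bits))) {
    s <- 0L
    for (i in seq_len(n)) s <- s + bits[i, k]
    if (2L * s - n > gamma) {
      n_one <- n_one + 1L
      sum_delta <- sum_delta + (2L * s - n)
    } else if (n - 2L * s > gamma) {
      # zero-similar: contributes to neither numerator nor denominator
    } else {
      n_dis <- n_dis + 1L
    }
  }
  if (n_one + n_dis == 0L) 0 else sum_delta / (n * (n_one + n_dis))
}

# leave-one-out recomputation from scratch (re-subsets the matrix each time)
oracle_complementary <- function(bits, gamma_policy = "parity") {
  n <- nrow(bits)
  g <- if (identical(gamma_policy, "parity")) (n - 1L) %% 2L else gamma_policy
  vapply(seq_len(n), function(i) {
    oracle_extended_jt(bits[-i, , drop = FALSE], g)
  }, numeric(1))
}

# scalar pairwise Tanimoto from the a/b/c contingency counts
oracle_tanimoto_pair <- function(x, y) {
  a <- sum(x == 1L & y == 1L)
  b <- sum(x == 1L & y == 0L)
  cc <- sum(x == 0L & y == 1L)
  if (a + b + cc == 0L) 0 else a / (a + b + cc)
}

random_bits <- function(n, m, density = 0.5) {
  matrix(as.integer(stats::runif(n * m) < density), n, m)
}
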