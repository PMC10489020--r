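#' Complementary (leave-one-out) similarity ranking of a library
#'
#' The complementary similarity of molecule i is the extended
#' Jaccard-Tanimoto similarity of the library with molecule i removed:
#' a low value means the rest of the set stays heterogeneous without i,
#' i.e. i sits in a high-density ("central", medoid-like) region, while a
#' high value means removing i makes the rest more coherent, i.e. i is an
#' outlier in the periphery.
#'
#' The whole ranking is computed in a single O(N M) pass: the column-sum
#' vector \eqn{\Sigma} is computed once and the fingerprint of each molecule
#' is subtracted from it (\eqn{\Sigma - m_i}), with the reduced set size
#' N - 1 used in the coincidence rules. The matrix is never re-summed per
#' molecule, and the result is identical (to the last bit) to recomputing
#' the extended similarity of every leave-one-out subset from scratch.
#'
#' @param x an [fpmatrix] or binary matrix with at least 3 rows.
#' @param gamma coincidence-threshold policy. `"parity"` (default)
#'   re-derives the threshold at the reduced set size, i.e.
#'   `(N - 1) %% 2`; a fixed integer is used unchanged (and must satisfy
#'   `0 <= gamma < N - 1`).
#' @return object of class `comp_ranking`: list with `values` (length-N
#'   numeric vector of complementary similarities, in input row order),
#'   `order` (permutation of `1:N`, ascending by value, ties broken by the
#'   original index — medoid first, top outlier last), `ids`, `n`,
#'   `gamma_policy` and `gamma` (the integer used at size N - 1).
#' @examples
#' # three identical molecules and one singleton: the singleton is the outlier
#' m <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
#' r <- complementary_similarity(m)
#' r$values   # 0 0 0 1
#' outlier_index(r)
#' @export
complementary_similarity <- function(x, gamma = "parity") {
  b <- fp_bits(x)
  n <- nrow(b)
  if (n < 3L) stop("need at least 3 molecules (each leave-one-out set must have >= 2)")
  m <- n - 1L
  g <- resolve_gamma(gamma, m)
  sums <- colSums(b)
  # signed Delta of the leave-one-out set, one row per left-out molecule:
  # 2 * (Sigma - m_i) - (N - 1)
  d <- matrix(2L * sums - m, nrow = n, ncol = ncol(b), byrow = TRUE) - 2L * b
  one <- d > g
  dis <- !(one | (-d > g))
  num <- rowSums(d * one)                  # integer-valued
  den <- rowSums(one) + rowSums(dis)
  zero_den <- den == 0
  if (any(zero_den)) {
    warning(sprintf(
      "%d leave-one-out set(s) had no 1-similar or dissimilar columns; their complementary similarity is defined as 0",
      sum(zero_den)))
  }
  values <- ifelse(zero_den, 0, num / (m * den))
  ord <- order(values, seq_len(n))
  structure(list(values = values, order = ord, ids = fp_ids(x), n = n,
                 gamma_policy = if (identical(gamma, "parity")) "parity" else "fixed",
                 gamma = g),
            class = "comp_ranking")
}

#' @export
print.comp_ranking <- function(x, ...) {
  cat(sprintf("Complementary similarity ranking of %d molecules (gamma = %d at size N-1%s)\n",
              x$n, x$gamma,
              if (x$gamma_policy == "parity") ", parity policy" else ""))
  cat(sprintf("  medoid:  %s (value %.6f)\n",
              x$ids[medoid_index(x)], x$values[medoid_index(x)]))
  cat(sprintf("  outlier: %s (value %.6f)\n",
              x$ids[outlier_index(x)], x$values[outlier_index(x)]))
  invisible(x)
}

#' @export
as.data.frame.comp_ranking <- function(x, ...) {
  data.frame(id = x$ids, complementary_similarity = x$values,
             rank = match(seq_len(x$n), x$order))
}

#' Medoid and outlier of a complementary ranking
#'
#' The medoid is the molecule whose removal leaves the most heterogeneous
#' set (lowest complementary similarity, most central); the outlier is the
#' molecule with the highest complementary similarity (most peripheral).
#' Ties are broken by the original row index.
#'
#' @param ranking a [complementary_similarity()] result.
#' @return a single row index into the original matrix.
#' @export
medoid_index <- function(ranking) {
  stopifnot(inherits(ranking, "comp_ranking"))
  ranking$order[1L]
}

#' @rdname medoid_index
#' @export
outlier_index <- function(ranking) {
  stopifnot(inherits(ranking, "comp_ranking"))
  ranking$order[ranking$n]
}
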