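#' Per-column bit sums of a fingerprint set
#'
#' First step of the extended (n-ary) similarity calculation: the vector
#' \eqn{\Sigma = (\sigma_1, \ldots, \sigma_M)} of column sums over the set
#' (or a subset) of fingerprints, plus the number of objects summed.
#'
#' @param x an [fpmatrix] or binary matrix.
#' @param subset optional integer vector of distinct row indices; if given,
#'   sums are taken over those rows only.
#' @return list with `sigma` (integer vector of length M) and `n_objects`.
#' @examples
#' column_sums(rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1)))
#' @export
column_sums <- function(x, subset = NULL) {
  b <- fp_bits(x)
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (length(subset) == 0L) stop("similarity of an empty set is undefined")
    if (anyDuplicated(subset)) stop("subset indices must be distinct")
    if (any(subset < 1L | subset > nrow(b))) stop("subset index out of range")
    b <- b[subset, , drop = FALSE]
  }
  list(sigma = as.integer(colSums(b)), n_objects = nrow(b))
}

# resolve the coincidence threshold gamma for a set of n objects.
# "parity" is the default policy: gamma = n mod 2, so that the similarity
# margin is corrected for odd set sizes.
resolve_gamma <- function(gamma, n) {
  if (identical(gamma, "parity")) return(n %% 2L)
  g <- as.integer(gamma)
  if (length(g) != 1L || is.na(g) || g < 0L) {
    stop("gamma must be \"parity\" or a single non-negative integer")
  }
  if (g >= n) {
    stop(sprintf(
      "gamma (%d) must be smaller than the number of objects (%d): every column would be dissimilar",
      g, n))
  }
  g
}

#' Coincidence-threshold classification of fingerprint columns
#'
#' Classifies every bit column of a set of N fingerprints as 1-similar
#' (mostly on), 0-similar (mostly off) or dissimilar, using the coincidence
#' threshold \eqn{\gamma}: a column with sum \eqn{\sigma_k} is 1-similar iff
#' \eqn{2\sigma_k - N > \gamma}, 0-similar iff \eqn{N - 2\sigma_k > \gamma},
#' and dissimilar otherwise. Also records
#' \eqn{\Delta\sigma_k = |2\sigma_k - N|} and the weight functions
#' \eqn{f_s(\Delta\sigma_k) = \Delta\sigma_k / N} and
#' \eqn{f_d(\Delta\sigma_k) = 1 - (\Delta\sigma_k - N \bmod 2)/N}.
#'
#' @param sums result of [column_sums()], or a list with elements `sigma`
#'   and `n_objects`.
#' @param gamma coincidence threshold: `"parity"` (default, `N %% 2`) or a
#'   single integer with `0 <= gamma < N`.
#' @return list of class `column_classification` with `label` (factor with
#'   levels one_similar / zero_similar / dissimilar), `delta`, `fs`, `fd`,
#'   `n_objects` and `gamma`.
#' @examples
#' s <- column_sums(rbind(c(1, 1, 0, 1), c(1, 0, 0, 1), c(1, 1, 1, 0)))
#' classify_columns(s, gamma = 1)
#' @export
classify_columns <- function(sums, gamma = "parity") {
  sigma <- as.integer(sums$sigma)
  n <- as.integer(sums$n_objects)
  if (any(sigma < 0L) || any(sigma > n)) {
    stop("column sums must lie in [0, n_objects]")
  }
  g <- resolve_gamma(gamma, n)
  d_signed <- 2L * sigma - n
  one <- d_signed > g
  zero <- -d_signed > g
  label <- rep("dissimilar", length(sigma))
  label[one] <- "one_similar"
  label[zero] <- "zero_similar"
  delta <- abs(d_signed)
  structure(list(
    label = factor(label, levels = c("one_similar", "zero_similar", "dissimilar")),
    delta = delta,
    fs = delta / n,
    fd = 1 - (delta - n %% 2L) / n,
    n_objects = n,
    gamma = g
  ), class = "column_classification")
}

#' Extended (n-ary) Jaccard-Tanimoto similarity of a set of fingerprints
#'
#' One similarity value for a whole set of N binary fingerprints, computed
#' from column sums in O(N M) rather than from all N(N-1)/2 pairs. Columns
#' are classified by the coincidence threshold (see [classify_columns()]);
#' the index is
#' \deqn{s_{eJT} = \frac{\sum_{1\text{-}s} \Delta\sigma_k / N}
#'                      {\#\{1\text{-}similar\} + \#\{dissimilar\}}}
#' i.e. a weighted count of 1-similar columns over 1-similar plus dissimilar
#' columns. With N = 2 and gamma = 0 this reduces exactly to the classical
#' pairwise Tanimoto coefficient a/(a + b + c).
#'
#' @param x an [fpmatrix], a binary matrix, or the result of
#'   [column_sums()].
#' @param gamma coincidence threshold, `"parity"` (default) or an integer.
#' @param subset optional row subset (passed to [column_sums()]).
#' @param weighted logical; if `TRUE` use the fully weighted variant, in
#'   which the denominator weighs 1-similar columns by \eqn{f_s} and
#'   dissimilar columns by \eqn{f_d} instead of counting them. The default
#'   `FALSE` is the plain counting denominator.
#' @return object of class `extended_similarity`: list with `value` (in
#'   [0, 1]), `classification`, `n_objects`, `gamma` and `weighted`.
#'   When no column is 1-similar or dissimilar (denominator zero) the value
#'   is defined as 0 and a warning is raised.
#' @examples
#' extended_jt(rbind(c(1, 1, 0, 1), c(1, 0, 0, 1), c(1, 1, 1, 0)), gamma = 1)
#' @export
extended_jt <- function(x, gamma = "parity", subset = NULL, weighted = FALSE) {
  sums <- if (is.list(x) && !inherits(x, "fpmatrix") &&
              all(c("sigma", "n_objects") %in% names(x))) {
    x
  } else {
    column_sums(x, subset = subset)
  }
  if (sums$n_objects < 2L) {
    warning("extended similarity of a single object is degenerate (every bit coincides with itself)")
  }
  cls <- classify_columns(sums, gamma)
  one <- cls$label == "one_similar"
  dis <- cls$label == "dissimilar"
  n <- cls$n_objects
  value <- if (weighted) {
    num <- sum(cls$fs[one])
    den <- num + sum(cls$fd[dis])
    if (den == 0) {
      warning("no 1-similar or dissimilar columns: extended similarity defined as 0")
      0
    } else num / den
  } else {
    den <- sum(one) + sum(dis)
    if (den == 0) {
      warning("no 1-similar or dissimilar columns: extended similarity defined as 0")
      0
    } else sum(cls$delta[one]) / (n * den)
  }
  structure(list(value = value, classification = cls, n_objects = n,
                 gamma = cls$gamma, weighted = weighted),
            class = "extended_similarity")
}

#' @export
print.extended_similarity <- function(x, ...) {
  tab <- table(x$classification$label)
  cat(sprintf("Extended Jaccard-Tanimoto similarity: %.6f\n", x$value))
  cat(sprintf("  N = %d objects, gamma = %d%s\n", x$n_objects, x$gamma,
              if (x$weighted) " (weighted denominator)" else ""))
  cat(sprintf("  columns: %d 1-similar, %d 0-similar, %d dissimilar\n",
              tab[["one_similar"]], tab[["zero_similar"]], tab[["dissimilar"]]))
  invisible(x)
}

#' Pairwise Jaccard-Tanimoto similarity matrix
#'
#' The classical N x N similarity matrix with entries a/(a + b + c), where
#' a is the number of shared on-bits of rows i and j and b, c count the
#' exclusive on-bits. A pair of all-zero fingerprints gets similarity 0 by
#' convention; the diagonal is 1 for every fingerprint with at least one
#' on-bit.
#'
#' @param x an [fpmatrix] or binary matrix with at least 2 rows.
#' @return N x N symmetric numeric matrix with molecule ids as dimnames.
#' @examples
#' pairwise_tanimoto(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
pairwise_tanimoto <- function(x) {
  b <- fp_bits(x)
  if (nrow(b) < 2L) stop("need at least 2 fingerprints")
  a <- tcrossprod(b)                       # shared on-bits
  on <- diag(a)                            # per-row on-bit counts
  union <- outer(on, on, "+") - a
  sim <- ifelse(union == 0, 0, a / union)
  ids <- fp_ids(x)
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Similarity feature rows for a satellite subset
#'
#' Returns the S x N matrix whose row s holds the Tanimoto similarities of
#' satellite s to all N molecules of the library (including itself). These
#' rows are exactly the corresponding rows of [pairwise_tanimoto()], but are
#' computed directly from the S and N bit matrices so that a map can be
#' built without ever forming the full N x N matrix.
#'
#' @param x an [fpmatrix] or binary matrix (the full library).
#' @param satellites integer vector of distinct, in-range row indices.
#' @return S x N numeric matrix; rownames are the satellite ids.
#' @export
satellite_features <- function(x, satellites) {
  b <- fp_bits(x)
  satellites <- as.integer(satellites)
  if (length(satellites) == 0L) stop("satellite set must not be empty")
  if (anyDuplicated(satellites)) stop("satellite indices must be distinct")
  if (any(satellites < 1L | satellites > nrow(b))) stop("satellite index out of range")
  s <- b[satellites, , drop = FALSE]
  a <- tcrossprod(s, b)
  on_s <- rowSums(s)
  on_all <- rowSums(b)
  union <- outer(on_s, on_all, "+") - a
  sim <- ifelse(union == 0, 0, a / union)
  dimnames(sim) <- list(fp_ids(x)[satellites], fp_ids(x))
  sim
}
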