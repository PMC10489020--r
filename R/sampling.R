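#' Order a library for chemical-satellite selection
#'
#' Turns a complementary-similarity ranking into a full ordering of the
#' library; the satellite selection of size s is the first s entries
#' (selections are nested by construction). Five strategies are available:
#'
#' * `medoid`: ascending complementary similarity — sample the chemical
#'   space from the centre outwards.
#' * `periphery`: descending complementary similarity — sample from the
#'   outside in.
#' * `medoid_periphery`: alternate the two ends; odd picks (1, 3, 5, ...)
#'   come from the medoid region, even picks (2, 4, 6, ...) from the
#'   outlier region, until the two pointers meet.
#' * `uniform`: split the ascending order into `n_batches` contiguous
#'   batches (the first `N %% n_batches` batches take one extra element)
#'   and pick round-robin, one molecule from each batch per cycle, in
#'   ascending complementary-similarity order within each batch.
#' * `random`: a uniform shuffle without replacement under `seed`, the
#'   baseline the structured strategies are compared against.
#'
#' @param ranking a [complementary_similarity()] result.
#' @param method one of `"medoid"`, `"medoid_periphery"`, `"uniform"`,
#'   `"periphery"`, `"random"`.
#' @param seed integer; required when `method = "random"`, ignored (with a
#'   warning) otherwise. The caller's RNG state is left untouched.
#' @param n_batches number of batches for `uniform` (default 5); must not
#'   exceed the library size.
#' @return object of class `satellite_selection`: list with `method`,
#'   `order` (permutation of `1:N`), `ids`, `seed`, `n_batches`.
#' @examples
#' m <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
#' r <- complementary_similarity(m)
#' sample_satellites(r, "medoid_periphery")$order
#' @export
sample_satellites <- function(ranking,
                              method = c("medoid", "medoid_periphery",
                                         "uniform", "periphery", "random"),
                              seed = NULL, n_batches = 5L) {
  stopifnot(inherits(ranking, "comp_ranking"))
  method <- match.arg(method)
  o <- ranking$order
  n <- ranking$n
  if (!is.null(seed) && method != "random") {
    warning("seed is only used by the random method; ignoring it")
    seed <- NULL
  }
  ord <- switch(method,
    medoid = o,
    periphery = rev(o),
    medoid_periphery = {
      h <- ceiling(n / 2)
      idx <- as.vector(rbind(seq_len(h), n + 1L - seq_len(h)))[seq_len(n)]
      o[idx]
    },
    uniform = {
      nb <- as.integer(n_batches)
      if (nb < 1L || nb > n) stop("n_batches must be between 1 and the library size")
      sizes <- rep(n %/% nb, nb) + c(rep(1L, n %% nb), rep(0L, nb - n %% nb))
      batches <- split(o, rep(seq_len(nb), times = sizes))
      picks <- integer(0)
      for (r in seq_len(max(sizes))) {
        for (bt in batches) if (length(bt) >= r) picks <- c(picks, bt[r])
      }
      picks
    },
    random = {
      if (is.null(seed)) stop("the random method requires a seed")
      with_preserved_rng({
        set.seed(as.integer(seed))
        sample(n)
      })
    })
  structure(list(method = method, order = ord, ids = ranking$ids,
                 seed = if (!is.null(seed)) as.integer(seed) else NULL,
                 n_batches = if (method == "uniform") as.integer(n_batches) else NULL),
            class = "satellite_selection")
}

#' @export
print.satellite_selection <- function(x, ...) {
  extra <- if (x$method == "random") sprintf(" (seed %d)", x$seed)
           else if (x$method == "uniform") sprintf(" (%d batches)", x$n_batches)
           else ""
  cat(sprintf("Satellite selection: %s%s over %d molecules\n",
              x$method, extra, length(x$order)))
  k <- min(6L, length(x$order))
  cat("  first picks:", paste(x$ids[x$order[seq_len(k)]], collapse = ", "),
      if (length(x$order) > k) "..." else "", "\n")
  invisible(x)
}

#' First k satellites of a selection
#'
#' @param selection a [sample_satellites()] result.
#' @param k number of satellites, `1 <= k <= N`.
#' @return integer vector of the first `k` row indices of the selection
#'   order. Because orders are full permutations, `first_k(sel, k)` is
#'   always a prefix of `first_k(sel, k + 1)`.
#' @export
first_k <- function(selection, k) {
  stopifnot(inherits(selection, "satellite_selection"))
  k <- as.integer(k)
  n <- length(selection$order)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stop(sprintf("k must be in [1, %d]", n))
  }
  selection$order[seq_len(k)]
}

# evaluate expr with the caller's RNG state saved and restored, so seeded
# sampling does not perturb the session's random stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
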