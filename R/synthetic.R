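#' Generate a clustered synthetic fingerprint library
#'
#' Emulates the structure the satellite sampling strategies are supposed to
#' detect — dense clusters plus isolated outliers — with a Bernoulli
#' template-noise model: each cluster draws a random binary template with
#' the given on-bit density, members copy the template with independent
#' per-bit flips at `flip_prob`, and singletons are independent random
#' fingerprints at the template density. With `flip_prob = 0` cluster
#' members are identical; a given `seed` always reproduces the same
#' library bit for bit.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param cluster_sizes integer vector of cluster sizes (length
#'   `n_clusters`); default 20 molecules per cluster.
#' @param n_bits fingerprint length (default 128).
#' @param template_density probability of an on-bit in a template, in
#'   (0, 1); default 0.30, a typical on-bit density of short structural
#'   fingerprints.
#' @param flip_prob per-bit flip probability within a cluster, in
#'   [0, 0.5); default 0.05 (tight clusters).
#' @param n_singletons number of unclustered outlier molecules (default 5).
#' @param seed integer seed; required for reproducibility, the caller's
#'   RNG state is preserved.
#' @return list with `fingerprints` (an [fpmatrix], family `"synthetic"`),
#'   `labels` (character: `"cluster_1"`, ..., `"singleton"`) and `spec`
#'   (the generating parameters). Total size must be at least 3.
#' @examples
#' lib <- generate_library(n_clusters = 1, cluster_sizes = 20,
#'                         flip_prob = 0.02, n_singletons = 3, seed = 1)
#' table(lib$labels)
#' @export
generate_library <- function(n_clusters = 3L,
                             cluster_sizes = rep(20L, n_clusters),
                             n_bits = 128L,
                             template_density = 0.30,
                             flip_prob = 0.05,
                             n_singletons = 5L,
                             seed = NULL) {
  n_clusters <- as.integer(n_clusters)
  cluster_sizes <- as.integer(cluster_sizes)
  n_bits <- as.integer(n_bits)
  n_singletons <- as.integer(n_singletons)
  if (n_clusters < 1L || length(cluster_sizes) != n_clusters || any(cluster_sizes < 1L)) {
    stop("cluster_sizes must give a positive size for each of the n_clusters clusters")
  }
  if (template_density <= 0 || template_density >= 1) {
    stop("template_density must lie strictly between 0 and 1")
  }
  if (flip_prob < 0 || flip_prob >= 0.5) {
    stop("flip_prob must lie in [0, 0.5): at 0.5 cluster membership carries no signal")
  }
  if (n_singletons < 0L) stop("n_singletons must be non-negative")
  n <- sum(cluster_sizes) + n_singletons
  if (n < 3L) stop("total library size must be at least 3")
  draw <- function() {
    rows <- vector("list", n)
    labels <- character(n)
    at <- 1L
    for (cl in seq_len(n_clusters)) {
      template <- stats::rbinom(n_bits, 1L, template_density)
      for (j in seq_len(cluster_sizes[cl])) {
        flips <- stats::rbinom(n_bits, 1L, flip_prob)
        rows[[at]] <- as.integer(xor(template, flips))
        labels[at] <- paste0("cluster_", cl)
        at <- at + 1L
      }
    }
    for (j in seq_len(n_singletons)) {
      rows[[at]] <- stats::rbinom(n_bits, 1L, template_density)
      labels[at] <- "singleton"
      at <- at + 1L
    }
    bits <- do.call(rbind, rows)
    list(
      fingerprints = fpmatrix(bits, ids = sprintf("syn_%03d", seq_len(n)),
                              family = "synthetic"),
      labels = labels,
      spec = list(n_clusters = n_clusters, cluster_sizes = cluster_sizes,
                  n_bits = n_bits, template_density = template_density,
                  flip_prob = flip_prob, n_singletons = n_singletons,
                  seed = seed)
    )
  }
  if (is.null(seed)) draw()
  else with_preserved_rng({ set.seed(as.integer(seed)); draw() })
}
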