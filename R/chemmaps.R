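#' Two-component PCA embedding of a similarity (feature) matrix
#'
#' Columns are mean-centred (never variance-scaled) and the rows are
#' projected onto the first two principal components by exact SVD. The map
#' geometry — all pairwise distances — is invariant under the per-component
#' sign ambiguity of PCA. If the matrix has rank < 2 the missing component
#' is a zero column.
#'
#' @param m K x F numeric matrix, K >= 2; rows are the embedded objects.
#' @param ids optional object identifiers (default: rownames, then
#'   `obj_1...`).
#' @return object of class `chemmap_embedding`: list with `scores`
#'   (K x 2), `explained_variance` (length 2, non-increasing) and `ids`.
#' @export
pca_embed <- function(m, ids = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 objects to embed")
  if (is.null(ids)) ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("obj_", seq_len(nrow(m)))
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- ncol(p$x)
  scores <- matrix(0, nrow(m), 2L)
  scores[, seq_len(min(2L, k))] <- p$x[, seq_len(min(2L, k)), drop = FALSE]
  ev <- c(p$sdev^2, 0, 0)[1:2]
  colnames(scores) <- c("PC1", "PC2")
  rownames(scores) <- ids
  structure(list(scores = scores, explained_variance = ev, ids = ids),
            class = "chemmap_embedding")
}

#' @export
print.chemmap_embedding <- function(x, ...) {
  tot <- sum(x$explained_variance)
  cat(sprintf("2-PC embedding of %d objects (PC1 %.1f%%, PC2 %.1f%% of top-2 variance)\n",
              nrow(x$scores),
              if (tot > 0) 100 * x$explained_variance[1] / tot else NA_real_,
              if (tot > 0) 100 * x$explained_variance[2] / tot else NA_real_))
  invisible(x)
}

#' Pairwise Euclidean distances in PC-score space
#'
#' @param embedding a [pca_embed()] result.
#' @return a `dist` object (condensed vector of the K(K-1)/2 distances for
#'   i < j in canonical order).
#' @export
pc_distances <- function(embedding) {
  stopifnot(inherits(embedding, "chemmap_embedding"))
  stats::dist(embedding$scores)
}

#' Correlation between two sets of map distances
#'
#' Pearson correlation r between two condensed distance vectors over the
#' same object pairs, and its square. Because only distances enter, the
#' measure is independent of the orientation (rotation, reflection, PC sign)
#' of either map.
#'
#' @param d1,d2 `dist` objects or numeric vectors of equal length >= 2,
#'   in the same pair order.
#' @return list with `r` and `r_squared`.
#' @export
distance_correlation <- function(d1, d2) {
  v1 <- as.numeric(d1)
  v2 <- as.numeric(d2)
  if (length(v1) != length(v2)) stop("distance sets must have equal length")
  if (length(v1) < 2L) stop("need at least 2 pairs to correlate")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("distance correlation undefined: one of the distance sets has zero variance")
  }
  r <- stats::cor(v1, v2)
  list(r = r, r_squared = r^2)
}

# correlation for internal curve building: degenerate (zero-variance)
# configurations yield NA instead of an error, with one warning
curve_cor <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Backward validation of a satellite map
#'
#' The backward approach is the proof-of-principle validation: embed the
#' full library once through PCA of its N x N Tanimoto similarity matrix,
#' take its pairwise PC-score distances as the reference, then for every
#' satellite count s = 3 ... N embed the S x N satellite feature matrix
#' (satellites as objects, similarities to all N molecules as features) and
#' correlate the satellite-pair distances of that reduced map against the
#' distances between the same satellites in the reference map. The smallest
#' s whose metric reaches the threshold is the satellite budget the
#' strategy needs.
#'
#' @param x an [fpmatrix] or binary matrix with N >= 4 rows.
#' @param selection a [sample_satellites()] result over the same library.
#' @param threshold correlation quality required, default 0.90 ("at least",
#'   i.e. `>=`).
#' @param metric `"r2"` (default) applies the threshold to the squared
#'   Pearson correlation, `"r"` to the correlation itself.
#' @return object of class `chemmap_curve` (see [chemmap()]), with one
#'   curve point per satellite count from 3 to N.
#' @export
backward_run <- function(x, selection, threshold = 0.90,
                         metric = c("r2", "r")) {
  metric <- match.arg(metric)
  stopifnot(inherits(selection, "satellite_selection"))
  b <- fp_bits(x)
  n <- nrow(b)
  if (n < 4L) stop("backward validation needs at least 4 molecules")
  if (length(selection$order) != n) stop("selection and matrix sizes differ")
  sim <- pairwise_tanimoto(x)
  ref <- pca_embed(sim, ids = fp_ids(x))
  dref <- as.matrix(pc_distances(ref))
  sizes <- 3:n
  r <- vapply(sizes, function(s) {
    idx <- selection$order[seq_len(s)]
    emb <- pca_embed(sim[idx, , drop = FALSE])
    curve_cor(stats::dist(emb$scores), stats::as.dist(dref[idx, idx]))
  }, numeric(1))
  new_chemmap_curve(mode = "backward", sizes = sizes, r = r, n = n,
                    method = selection$method, metric = metric,
                    threshold = threshold, strict = FALSE,
                    family = if (inherits(x, "fpmatrix")) x$family else "custom",
                    reference = ref)
}

#' Forward construction of a satellite map
#'
#' The forward approach avoids the full N x N PCA entirely: start with a
#' fraction of the library (default 25%) as satellites, embed their
#' S x N feature matrix, then repeatedly add the next increment (default
#' 5%) of the selection order, re-embed, and correlate the distances among
#' the previous satellite set — the elements the consecutive maps have in
#' common — between the updated and the former map. The run stops when the
#' metric exceeds the threshold (self-consistency reached) or the whole
#' library has been used.
#'
#' @inheritParams backward_run
#' @param start initial satellite fraction (default 0.25); `ceiling(start
#'   * N)` must be at least 3.
#' @param step fraction added per iteration (default 0.05), converted to a
#'   count by ceiling so at least one molecule is added.
#' @param threshold correlation quality required, default 0.90 ("greater
#'   than", i.e. strict `>`).
#' @return object of class `chemmap_curve`, one point per growth step
#'   (the first comparison is between the start set and start + step).
#' @export
forward_run <- function(x, selection, start = 0.25, step = 0.05,
                        threshold = 0.90, metric = c("r2", "r")) {
  metric <- match.arg(metric)
  stopifnot(inherits(selection, "satellite_selection"))
  b <- fp_bits(x)
  n <- nrow(b)
  if (length(selection$order) != n) stop("selection and matrix sizes differ")
  s0 <- as.integer(ceiling(start * n))
  if (s0 < 3L) stop("start fraction too small: need ceiling(start * N) >= 3")
  inc <- max(1L, as.integer(ceiling(step * n)))
  prev_idx <- selection$order[seq_len(s0)]
  prev_emb <- pca_embed(satellite_features(x, prev_idx))
  sizes <- integer(0)
  r <- numeric(0)
  s <- s0
  while (s < n) {
    s <- min(n, s + inc)
    idx <- selection$order[seq_len(s)]
    emb <- pca_embed(satellite_features(x, idx))
    # nested selections: the former satellite set is exactly the first
    # length(prev_idx) rows of the updated embedding
    common <- seq_along(prev_idx)
    rr <- curve_cor(stats::dist(emb$scores[common, , drop = FALSE]),
                    stats::dist(prev_emb$scores))
    sizes <- c(sizes, s)
    r <- c(r, rr)
    met <- if (metric == "r2") rr^2 else rr
    if (!is.na(met) && met > threshold) break
    prev_idx <- idx
    prev_emb <- emb
  }
  new_chemmap_curve(mode = "forward", sizes = sizes, r = r, n = n,
                    method = selection$method, metric = metric,
                    threshold = threshold, strict = TRUE,
                    family = if (inherits(x, "fpmatrix")) x$family else "custom",
                    reference = NULL)
}

# shared constructor for backward/forward quality curves
new_chemmap_curve <- function(mode, sizes, r, n, method, metric, threshold,
                              strict, family, reference) {
  curve <- data.frame(n_satellites = sizes, fraction = sizes / n,
                      r = r, r_squared = r^2)
  met <- if (metric == "r2") curve$r_squared else curve$r
  hit <- if (strict) which(!is.na(met) & met > threshold)
         else which(!is.na(met) & met >= threshold)
  structure(list(curve = curve, mode = mode, method = method,
                 metric = metric, threshold = threshold, n = n,
                 fingerprint = family,
                 n_reached = if (length(hit)) curve$n_satellites[hit[1L]] else NA_integer_,
                 fraction_reached = if (length(hit)) curve$fraction[hit[1L]] else NA_real_,
                 reference = reference),
            class = "chemmap_curve")
}

#' @export
print.chemmap_curve <- function(x, ...) {
  cat(sprintf("ChemMaps %s run: %s sampling, %d molecules (%s fingerprints)\n",
              x$mode, x$method, x$n, x$fingerprint))
  cat(sprintf("  metric: %s, threshold %.2f (%s)\n",
              if (x$metric == "r2") "r-squared" else "Pearson r", x$threshold,
              if (x$mode == "forward") "strict >" else ">="))
  if (is.na(x$n_reached)) {
    cat("  threshold not reached on this curve\n")
  } else {
    cat(sprintf("  reached at %d satellites (%.1f%% of the library)\n",
                x$n_reached, 100 * x$fraction_reached))
  }
  invisible(x)
}

#' @export
summary.chemmap_curve <- function(object, ...) {
  print(object)
  cat("\nQuality curve:\n")
  print(utils::head(object$curve, 10))
  if (nrow(object$curve) > 10) cat(sprintf("  ... %d points total\n", nrow(object$curve)))
  invisible(object$curve)
}

#' @export
plot.chemmap_curve <- function(x, ...) {
  met <- if (x$metric == "r2") x$curve$r_squared else x$curve$r
  graphics::plot(x$curve$fraction, met, type = "b", pch = 16, cex = 0.6,
                 xlab = "fraction of library used as satellites",
                 ylab = if (x$metric == "r2") expression(R^2) else "r",
                 main = sprintf("%s run, %s sampling", x$mode, x$method), ...)
  graphics::abline(h = x$threshold, lty = 2, col = "grey40")
  if (!is.na(x$fraction_reached)) {
    graphics::abline(v = x$fraction_reached, lty = 3, col = "grey60")
  }
  invisible(x)
}

#' Diversity summary of a fingerprint library
#'
#' Two global diversity measures: the mean of the N(N-1)/2 pairwise
#' Tanimoto similarities (lower = more diverse) and the mean pairwise
#' Euclidean distance between the molecules in the 2-PC embedding of the
#' full similarity matrix (higher = more spread out).
#'
#' @param x an [fpmatrix] or binary matrix, N >= 2.
#' @return object of class `diversity_summary`: list with `n`,
#'   `avg_pairwise_similarity` and `avg_pca_distance`.
#' @export
diversity_summary <- function(x) {
  sim <- pairwise_tanimoto(x)
  emb <- pca_embed(sim, ids = fp_ids(x))
  structure(list(
    n = nrow(sim),
    avg_pairwise_similarity = mean(sim[upper.tri(sim)]),
    avg_pca_distance = mean(pc_distances(emb))
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Library diversity (N = %d)\n", x$n))
  cat(sprintf("  average pairwise Tanimoto similarity: %.4f\n",
              x$avg_pairwise_similarity))
  cat(sprintf("  average pairwise PCA distance:        %.4f\n",
              x$avg_pca_distance))
  invisible(x)
}

#' Fit a satellite-based chemical-space map
#'
#' High-level entry point tying the pipeline together: rank the library by
#' complementary similarity, order it with a satellite sampling strategy,
#' and run the backward (validation against the full-matrix map) or forward
#' (incremental self-consistency) algorithm, returning the quality curve
#' and the satellite budget at which the map is considered reliable.
#'
#' @param x an [fpmatrix] or binary fingerprint matrix.
#' @param method satellite sampling strategy (see [sample_satellites()]).
#' @param mode `"backward"` or `"forward"`.
#' @param gamma coincidence-threshold policy for the complementary ranking.
#' @param threshold correlation quality required (default 0.90).
#' @param metric `"r2"` (default) or `"r"`.
#' @param start,step forward-mode fractions (see [forward_run()]).
#' @param seed seed for the `random` sampling method.
#' @param n_batches batches for the `uniform` method.
#' @return object of class `chemmap` (and `chemmap_curve`), additionally
#'   carrying the `ranking` and `selection` used and the matched call.
#' @examples
#' lib <- generate_library(seed = 7)
#' fit <- chemmap(lib$fingerprints, method = "medoid_periphery")
#' fit
#' @export
chemmap <- function(x,
                    method = c("medoid_periphery", "medoid", "uniform",
                               "periphery", "random"),
                    mode = c("backward", "forward"),
                    gamma = "parity", threshold = 0.90,
                    metric = c("r2", "r"),
                    start = 0.25, step = 0.05,
                    seed = NULL, n_batches = 5L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  ranking <- complementary_similarity(x, gamma = gamma)
  selection <- sample_satellites(ranking, method, seed = seed,
                                 n_batches = n_batches)
  fit <- if (mode == "backward") {
    backward_run(x, selection, threshold = threshold, metric = metric)
  } else {
    forward_run(x, selection, start = start, step = step,
                threshold = threshold, metric = metric)
  }
  fit$ranking <- ranking
  fit$selection <- selection
  fit$call <- match.call()
  class(fit) <- c("chemmap", class(fit))
  fit
}

#' @export
print.chemmap <- function(x, ...) {
  cat("Satellite chemical-space map\n")
  cat("Call: "); print(x$call)
  NextMethod()
}
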