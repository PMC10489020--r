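test_that("PCA embedding centres columns, keeps two components, pads rank-1 data", {
  # collinear points: all variance on PC1, PC2 exactly zero
  m <- cbind(c(0, 1, 2, 3), c(0, 2, 4, 6))
  emb <- pca_embed(m)
  expect_identical(dim(emb$scores), c(4L, 2L))
  expect_equal(emb$scores[, 2L], rep(0, 4), ignore_attr = TRUE)
  expect_equal(emb$explained_variance[2L], 0)
  expect_true(diff(emb$explained_variance) <= 0)

  # duplicated rows embed to identical scores
  dup <- rbind(c(1, 0, 2), c(1, 0, 2), c(0, 3, 1))
  edup <- pca_embed(dup)
  expect_equal(edup$scores[1L, ], edup$scores[2L, ], ignore_attr = TRUE)

  expect_error(pca_embed(matrix(1, 1L, 3L)), "at least 2")
})

test_that("PC distances are Euclidean, condensed, and sign-flip invariant", {
  emb <- structure(list(scores = rbind(c(0, 0), c(3, 4), c(0, 1)),
                        explained_variance = c(1, 1),
                        ids = c("a", "b", "c")),
                   class = "chemmap_embedding")
  d <- pc_distances(emb)
  expect_length(as.numeric(d), 3L)
  expect_equal(as.matrix(d)["1", "2"] , 5)

  flipped <- emb
  flipped$scores[, 1L] <- -flipped$scores[, 1L]
  expect_equal(as.numeric(pc_distances(flipped)), as.numeric(d))
})

test_that("distance correlation behaves like Pearson r on condensed vectors", {
  d1 <- c(1, 2, 3)
  expect_equal(distance_correlation(d1, 2 * d1)$r, 1)
  expect_equal(distance_correlation(d1, d1)$r_squared, 1)
  expect_equal(distance_correlation(d1, c(3, 2, 1))$r, -1)
  expect_error(distance_correlation(d1, c(1, 2)), "equal length")
  expect_error(distance_correlation(c(1, 1, 1), d1), "zero variance")
})

test_that("backward curve starts at 3 satellites and ends at exactly 1", {
  for (seed in c(5L, 17L)) {
    lib <- generate_library(n_clusters = 2L, cluster_sizes = c(15L, 10L),
                            n_bits = 96L, n_singletons = 3L, seed = seed)
    r <- complementary_similarity(lib$fingerprints)
    for (method in c("medoid_periphery", "uniform", "random")) {
      sel <- sample_satellites(r, method,
                               seed = if (method == "random") 1L else NULL)
      run <- backward_run(lib$fingerprints, sel)
      n <- lib$fingerprints$bits |> nrow()
      expect_identical(run$curve$n_satellites, 3:n)
      expect_equal(run$curve$fraction[nrow(run$curve)], 1)
      # endpoint identity: S = N reproduces the reference map geometry
      expect_equal(run$curve$r[nrow(run$curve)], 1, tolerance = 1e-9)
      expect_true(all(abs(run$curve$r[!is.na(run$curve$r)]) <= 1 + 1e-12))
    }
  }
})

test_that("backward curve values are invariant to molecule storage order", {
  # the property holds up to tie-breaking, so use a tie-free library
  set.seed(2)
  bits <- random_bits(22L, 200L)
  r <- complementary_similarity(bits)
  expect_identical(anyDuplicated(r$values), 0L)
  run <- backward_run(bits, sample_satellites(r, "medoid_periphery"))

  set.seed(99)
  perm <- sample(nrow(bits))
  bp <- bits[perm, , drop = FALSE]
  rp <- complementary_similarity(bp)
  runp <- backward_run(bp, sample_satellites(rp, "medoid_periphery"))
  # same molecules get selected in the same sequence, so the quality curve
  # is identical up to floating noise (values here are tie-free)
  expect_equal(runp$curve$r, run$curve$r, tolerance = 1e-8)
})

test_that("threshold bookkeeping honours metric choice and reports the first crossing", {
  lib <- generate_library(n_clusters = 1L, cluster_sizes = 25L, n_bits = 96L,
                          flip_prob = 0.03, n_singletons = 3L, seed = 31L)
  r <- complementary_similarity(lib$fingerprints)
  sel <- sample_satellites(r, "medoid_periphery")
  run <- backward_run(lib$fingerprints, sel, threshold = 0.90, metric = "r2")
  expect_false(is.na(run$n_reached))
  expect_lt(run$fraction_reached, 1)
  first_hit <- which(run$curve$r_squared >= 0.90)[1L]
  expect_identical(run$n_reached, run$curve$n_satellites[first_hit])

  run_r <- backward_run(lib$fingerprints, sel, threshold = 0.90, metric = "r")
  first_hit_r <- which(run_r$curve$r >= 0.90)[1L]
  expect_identical(run_r$n_reached, run_r$curve$n_satellites[first_hit_r])
})

test_that("forward runs compare consecutive maps over the common satellites", {
  lib <- generate_library(n_clusters = 2L, cluster_sizes = c(20L, 15L),
                          n_bits = 96L, n_singletons = 5L, seed = 43L)
  r <- complementary_similarity(lib$fingerprints)
  sel <- sample_satellites(r, "medoid_periphery")
  n <- length(sel$order)

  # a step covering the whole library in one addition: single comparison
  # over the pairs of the initial 25% set
  run1 <- forward_run(lib$fingerprints, sel, start = 0.25, step = 1.0,
                      threshold = 0.99)
  expect_identical(nrow(run1$curve), 1L)
  expect_identical(run1$curve$n_satellites, n)
  s0 <- ceiling(0.25 * n)
  emb_start <- pca_embed(satellite_features(lib$fingerprints, first_k(sel, s0)))
  emb_full <- pca_embed(satellite_features(lib$fingerprints, sel$order))
  expected_r <- distance_correlation(
    pc_distances(emb_start),
    dist(emb_full$scores[seq_len(s0), , drop = FALSE]))$r
  expect_equal(run1$curve$r, expected_r, tolerance = 1e-12)

  # default stepping: sizes grow by ceiling(0.05 N) and fractions increase
  run <- forward_run(lib$fingerprints, sel, threshold = 2)  # never stops early
  expect_true(all(diff(run$curve$fraction) > 0))
  expect_identical(run$curve$n_satellites[nrow(run$curve)], n)
  inc <- ceiling(0.05 * n)
  expect_identical(run$curve$n_satellites[1L], as.integer(min(n, s0 + inc)))
})

test_that("forward stopping rule is strict and desists at 100%", {
  lib <- generate_library(n_clusters = 1L, cluster_sizes = 30L, n_bits = 96L,
                          flip_prob = 0.02, n_singletons = 2L, seed = 53L)
  fit <- chemmap(lib$fingerprints, method = "medoid_periphery", mode = "forward")
  last <- nrow(fit$curve)
  if (!is.na(fit$n_reached)) {
    expect_gt(fit$curve$r_squared[last], 0.90)
    expect_identical(fit$n_reached, fit$curve$n_satellites[last])
    expect_lt(fit$fraction_reached, 1)   # low-diversity set stops early
  }
  # every point before the stop was at or below the threshold
  if (last > 1L) {
    expect_true(all(fit$curve$r_squared[seq_len(last - 1L)] <= 0.90))
  }
})

test_that("diversity summary matches the hand-counted toy and degenerate cases", {
  d <- diversity_summary(toy_abcd())
  expect_equal(d$avg_pairwise_similarity, 0.5)
  expect_identical(d$n, 4L)
  expect_gt(d$avg_pca_distance, 0)

  ident <- matrix(rep(c(1L, 0L, 1L, 1L), each = 5L), nrow = 5L)
  di <- diversity_summary(ident)
  expect_equal(di$avg_pairwise_similarity, 1)
  expect_equal(di$avg_pca_distance, 0)
})

test_that("fewer satellites suffice for low-diversity than high-diversity libraries", {
  frac_needed <- function(lib) {
    fit <- chemmap(lib$fingerprints, method = "medoid_periphery")
    if (is.na(fit$fraction_reached)) 1 else fit$fraction_reached
  }
  seeds <- 1:10
  low <- vapply(seeds, function(s) frac_needed(
    generate_library(n_clusters = 1L, cluster_sizes = 36L, n_bits = 96L,
                     flip_prob = 0.02, n_singletons = 4L, seed = s)), numeric(1))
  high <- vapply(seeds, function(s) frac_needed(
    generate_library(n_clusters = 4L, cluster_sizes = rep(9L, 4L), n_bits = 96L,
                     flip_prob = 0.25, n_singletons = 4L, seed = s)), numeric(1))
  expect_lte(mean(low), mean(high))
})

test_that("chemmap() carries its ranking, selection and call", {
  lib <- generate_library(seed = 63L)
  fit <- chemmap(lib$fingerprints, method = "uniform", n_batches = 5L)
  expect_s3_class(fit, "chemmap")
  expect_s3_class(fit$ranking, "comp_ranking")
  expect_identical(fit$selection$method, "uniform")
  expect_identical(fit$fingerprint, "synthetic")
  expect_output(print(fit), "uniform sampling")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
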