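# Shared micro-fixtures.

# three molecules, four bits: the worked extended-similarity example
micro_bits <- function() rbind(c(1L, 1L, 0L, 1L),
                               c(1L, 0L, 0L, 1L),
                               c(1L, 1L, 1L, 0L))

# A = B = C = [1,1,0] plus the singleton D = [0,0,1]
toy_abcd <- function() rbind(c(1L, 1L, 0L),
                             c(1L, 1L, 0L),
                             c(1L, 1L, 0L),
                             c(0L, 0L, 1L))

# a ranking whose ascending order is exactly 1..n (distinct values)
ranked_fixture <- function(n, m = 32L, seed = 42L) {
  lib <- generate_library(n_clusters = 1L, cluster_sizes = n - 2L,
                          n_bits = m, flip_prob = 0.1, n_singletons = 2L,
                          seed = seed)
  complementary_similarity(lib$fingerprints)
}

# synthetic ranking with hand-set values, for sampling-order tests
fake_ranking <- function(values) {
  n <- length(values)
  structure(list(values = values, order = order(values, seq_len(n)),
                 ids = paste0("m", seq_len(n)), n = n,
                 gamma_policy = "parity", gamma = (n - 1L) %% 2L),
            class = "comp_ranking")
}
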