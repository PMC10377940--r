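# Shared helpers: channel bundles for the worked examples and trimmed
# optimizer options for property-style loops.

gate_channels <- function(name) {
  j <- gate_joint(name)
  c1 <- channel_from_joint(j, 1)
  c2 <- channel_from_joint(j, 2)
  list(joint = j, p_t = c1$p_t, K1 = c1$K, K2 = c2$K,
       channels = list(c1$K, c2$K))
}

# Small search budget for randomized property loops; the assertions there
# are bracket/inequality checks that stay valid under weaker search.
tiny_opts <- function(seed = 0) {
  ii_opts(restarts = 2, max_iter = 15, n_dirs = 3, n_sample = 40,
          n_pairs = 40, max_pairs = 600, vertex_combo_cap = 2000,
          seed = seed)
}

# Moderate budget used where single fixture values are asserted.
std_opts <- function(seed = 0) ii_opts(seed = seed)

expect_bits <- function(actual, expected, tol = 1e-6) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("%.6f vs expected %.6f", actual, expected))
}

# Interval of an ii_measure result.
ii_interval <- function(r) c(r$lower, r$upper)

# Channels from a random joint for the first `n` sources.
joint_channels <- function(j, n = n_sources(j)) {
  cs <- lapply(seq_len(n), function(i) channel_from_joint(j, i))
  list(p_t = cs[[1]]$p_t, channels = lapply(cs, `[[`, "K"))
}
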