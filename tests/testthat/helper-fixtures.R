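# Shared small fixtures: everything is generated in code at test time.

# A compact cohort with clearly planted subtypes, cheap enough for repeated
# training runs inside tests.
small_spec <- function(seed = 1L, effect_size = 1.5, ...) {
  cohort_spec(n_id = 60L, n_hc = 20L, n_roi = 40L, n_skeleton = 50L,
              n_blocks = 4L, effect_size = effect_size,
              subtype_fractions = c(0.6, 0.4), seed = seed, ...)
}

# A small-but-real model configuration used where the full default
# architecture would be wastefully slow.
small_enc <- function() encoder_config(layer_dims = c(16L, 8L),
                                       heads = c(2L, 1L), latent_dim = 8L)
small_dec <- function() decoder_config(hidden_dims = c(8L, 16L))

# Hand-rolled Pearson correlation from the definition, for loop oracles.
pearson_def <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Deterministic toy graph: ring of n nodes plus one chord.
ring_graph <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    adj[i, j] <- adj[j, i] <- 1
  }
  adj[1, max(3L, n %/% 2L)] <- adj[max(3L, n %/% 2L), 1] <- 1
  adj
}

# Two well-separated Gaussian blobs in d dimensions.
two_blobs <- function(n_per = 20L, d = 16L, sep = 10, seed = 1L) {
  set.seed(seed)
  z <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d), n_per))
  z[seq_len(n_per), 1L] <- z[seq_len(n_per), 1L] + sep
  rownames(z) <- sprintf("S%03d", seq_len(2L * n_per))
  list(z = z, labels = rep(1:2, each = n_per))
}
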