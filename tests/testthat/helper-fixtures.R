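# Shared fixtures. Heavy trained-model experiments are computed lazily and
# cached so several test files can reuse one training run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

# small deterministic multichannel recording (not band-limited)
toy_recording <- function(n_ch = 4, n = 500, rate = 250, seed = 11) {
  set.seed(seed)
  tt <- seq_len(n) / rate
  data <- t(sapply(seq_len(n_ch), function(k) {
    sin(2 * pi * (5 + k) * tt) + 0.3 * cos(2 * pi * 11 * tt + k) +
      0.05 * rnorm(n)
  }))
  recording(data, rate = rate, channel_ids = seq_len(n_ch))
}

# identity-recovery experiment shared by the model/training/acceptance tests
identity_result <- function() {
  fixture("identity", function() {
    experiment_identity(seed = 1L, duration_s = 72,
                        run = training_run(preset = "satisfactory",
                                           seed = 1L, batch_size = 16L))
  })
}

mixture_result <- function() {
  fixture("mixture", function() {
    experiment_mixture(seed = 1L, duration_s = 72,
                       run = training_run(preset = "satisfactory",
                                          seed = 1L, batch_size = 16L))
  })
}

# tiny configuration for fast structural tests
tiny_config <- function(seed = 5L) {
  model_config(d_model = 16L, n_heads = 4L, seq_len = 16L, label_len = 8L,
               d_x = 4L, d_ff = 32L, dropout = 0, seed = seed)
}

# dense softmax attention by definitional nested loops (oracle)
dense_attention_oracle <- function(Q, K, V) {
  d <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    w <- exp(s - max(s))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}
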