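test_that("positional encoding matches its closed form and stays in [-1, 1]", {
  # pos = 0: sines are 0, cosines are 1
  pe0 <- positional_encode(0, L_x = 48, d_model = 128)
  expect_equal(pe0[seq(1, 127, by = 2)], rep(0, 64))
  expect_equal(pe0[seq(2, 128, by = 2)], rep(1, 64))

  # paired components are a sine/cosine of one angle
  for (pos in c(1, 7, 47)) {
    pe <- positional_encode(pos, 48, 128)
    expect_equal(pe[seq(1, 127, 2)]^2 + pe[seq(2, 128, 2)]^2, rep(1, 64))
    expect_true(all(pe >= -1 & pe <= 1))
  }

  # direct evaluation of the formula for pos = 1, pair j = 1
  pe1 <- positional_encode(1, L_x = 48, d_model = 128)
  ang <- 1 / (2 * 48)^(2 * 1 / 128)
  expect_equal(pe1[3], sin(ang))
  expect_equal(pe1[4], cos(ang))
})

test_that("sparsity measure: uniform floor, two-score closed form, oracle", {
  set.seed(3)
  # equal scores: M = log(L_K) exactly (query orthogonal to every key)
  K <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  q <- c(0, 0, 0, 2)
  expect_equal(sparsity_measure(q, K), log(3))

  # L_K = 2 with scores (c, 0): M = log(exp(c) + 1) - c/2
  d <- 4
  c_val <- 20
  K2 <- rbind(c(1, 0, 0, 0) * c_val * sqrt(d), c(0, 0, 0, 0))
  q2 <- c(1, 0, 0, 0)
  expect_equal(sparsity_measure(q2, K2), log(exp(c_val) + 1) - c_val / 2,
               tolerance = 1e-12)

  # random instances against a definitional loop
  for (rep in 1:20) {
    Lk <- sample(2:12, 1)
    d <- sample(2:8, 1)
    q <- rnorm(d)
    K <- matrix(rnorm(Lk * d), Lk)
    s <- sapply(seq_len(Lk), function(j) sum(q * K[j, ]) / sqrt(d))
    expect_equal(sparsity_measure(q, K), log(sum(exp(s))) - mean(s),
                 tolerance = 1e-10)
    expect_gte(sparsity_measure(q, K), log(Lk) - 1e-12)
  }
})

test_that("probsparse attention with all queries selected equals the dense oracle", {
  set.seed(17)
  for (rep in 1:100) {
    Lq <- sample(2:16, 1)
    Lk <- sample(2:16, 1)
    d <- sample(2:8, 1)
    Q <- matrix(rnorm(Lq * d), Lq)
    K <- matrix(rnorm(Lk * d), Lk)
    V <- matrix(rnorm(Lk * d), Lk)
    out <- probsparse_attention(Q, K, V, u = Lq, key_sample = Lk)
    expect_lt(max(abs(out - dense_attention_oracle(Q, K, V))), 1e-5)
  }
})

test_that("probsparse attention fill rules: constant V rows, u = 0", {
  set.seed(4)
  Q <- matrix(rnorm(12 * 4), 12)
  K <- matrix(rnorm(10 * 4), 10)
  v <- rnorm(4)
  V_const <- matrix(rep(v, each = 10), 10)
  for (u in c(0, 3, 12)) {
    out <- probsparse_attention(Q, K, V_const, u = u)
    expect_equal(out, matrix(rep(v, each = 12), 12), tolerance = 1e-12)
  }
  V <- matrix(rnorm(10 * 4), 10)
  out0 <- probsparse_attention(Q, K, V, u = 0)
  expect_equal(out0, matrix(rep(colMeans(V), each = 12), 12))
  expect_error(probsparse_attention(Q, K[, 1:2], V), "dimension mismatch")
})

test_that("with key subsampling every output row is a dense row or the value mean", {
  set.seed(6)
  Q <- matrix(rnorm(10 * 4), 10)
  K <- matrix(rnorm(8 * 4), 8)
  V <- matrix(rnorm(8 * 4), 8)
  dense <- dense_attention_oracle(Q, K, V)
  vbar <- colMeans(V)
  out <- probsparse_attention(Q, K, V, u = 4, key_sample = 3)
  matched <- vapply(seq_len(nrow(out)), function(i) {
    isTRUE(all.equal(out[i, ], dense[i, ], tolerance = 1e-8)) ||
      isTRUE(all.equal(out[i, ], vbar, tolerance = 1e-12))
  }, logical(1))
  expect_true(all(matched))
  expect_equal(sum(vapply(seq_len(nrow(out)), function(i) {
    isTRUE(all.equal(out[i, ], dense[i, ], tolerance = 1e-8))
  }, logical(1))), 4)
})

test_that("partial probsparse attention agrees with dense rows on selected queries", {
  # the C++ kernel behind the model: selected rows = dense attention,
  # unselected rows = mean of V
  ns <- asNamespace("eegcomplete")
  set.seed(9)
  Lq <- 12L; d <- 6L
  Q <- matrix(rnorm(Lq * d), Lq)
  K <- matrix(rnorm(Lq * d), Lq)
  V <- matrix(rnorm(Lq * d), Lq)
  res <- ns$.mha_forward_cpp(Q, K, V, 1L, Lq, Lq, 1L, FALSE, 5L)
  dense <- dense_attention_oracle(Q, K, V)
  sel <- as.logical(res$sel[, 1])
  expect_equal(sum(sel), 5)
  expect_equal(res$O[sel, ], dense[sel, ], tolerance = 1e-10)
  expect_equal(res$O[!sel, ],
               matrix(rep(colMeans(V), each = sum(!sel)), sum(!sel)),
               tolerance = 1e-12)
})

test_that("distilling halves the sequence length: 48 -> 24 -> 12, 7 -> 4", {
  set.seed(2)
  X <- matrix(rnorm(48 * 8), 48)
  d1 <- distill(X)
  expect_equal(nrow(d1), 24L)
  d2 <- distill(d1)
  expect_equal(nrow(d2), 12L)
  expect_equal(nrow(distill(matrix(rnorm(7 * 3), 7))), 4L)
  expect_error(distill(matrix(1, 1, 3)), ">= 2")
})

test_that("distill with identity taps is ELU followed by max pooling", {
  X <- matrix(c(-1, 2, -3, 4, 5, -6), ncol = 1)
  out <- distill(X)
  e <- c(exp(-1) - 1, 2, exp(-3) - 1, 4, 5, exp(-6) - 1)
  # windows (pad,1,2), (2,3,4), (4,5,6)
  expect_equal(as.numeric(out), c(max(e[1:2]), max(e[2:4]), max(e[4:6])))
})

test_that("forward pass has the contract shape and is deterministic", {
  cfg <- tiny_config()
  m <- ec_informer(cfg)
  set.seed(1)
  enc <- matrix(runif(cfg$seq_len * cfg$d_x), cfg$seq_len)
  dec <- matrix(runif(cfg$label_len * cfg$d_x), cfg$label_len)
  y1 <- forward(m, enc, dec)
  y2 <- forward(m, enc, dec)
  expect_equal(dim(y1), c(cfg$label_len, 1L))
  expect_identical(y1, y2)

  # default-size model emits a 24 x 1 label window
  m128 <- ec_informer(model_config(seed = 2L))
  enc48 <- matrix(runif(48 * 4), 48)
  dec24 <- matrix(runif(24 * 4), 24)
  expect_equal(dim(forward(m128, enc48, dec24)), c(24L, 1L))

  expect_error(forward(m, enc[1:5, ], dec), "shape mismatch")
  enc[1] <- NA
  expect_error(forward(m, enc, dec), "non-finite")
})

test_that("same seed gives identical weights; parameter count is fixed", {
  m1 <- ec_informer(model_config(seed = 7L))
  m2 <- ec_informer(model_config(seed = 7L))
  expect_identical(m1$params, m2$params)
  expect_equal(n_parameters(m1), n_parameters(m2))
  m3 <- ec_informer(model_config(seed = 8L))
  expect_equal(n_parameters(m1), n_parameters(m3))
})

test_that("backpropagation matches finite-difference gradients", {
  ns <- asNamespace("eegcomplete")
  cfg <- model_config(d_model = 8L, n_heads = 2L, seq_len = 8L,
                      label_len = 4L, d_x = 3L, d_ff = 12L, dropout = 0,
                      seed = 42L, sampling_factor = 1.2)
  m <- ec_informer(cfg)
  set.seed(7)
  B <- 2L
  Xenc <- matrix(runif(B * cfg$seq_len * cfg$d_x), B * cfg$seq_len)
  Xdec <- matrix(runif(B * cfg$label_len * cfg$d_x), B * cfg$label_len)
  Yt <- matrix(runif(B * cfg$label_len), ncol = 1)
  t_s <- cfg$seq_len - cfg$label_len
  lossfn <- function(p) {
    mean((ns$.model_forward(p, cfg, Xenc, Xdec, t_s)$Y - Yt)^2)
  }
  fw <- ns$.model_forward(m$params, cfg, Xenc, Xdec, t_s,
                          keep_cache = TRUE)
  g <- ns$.model_backward(m$params, cfg, fw$cache,
                          2 * (fw$Y - Yt) / (B * cfg$label_len))
  eps <- 1e-6
  p <- m$params
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(2, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("checkpoints round-trip the model, config and metadata", {
  m <- ec_informer(tiny_config())
  m$inputs <- c(1L, 8L, 12L, 20L)
  m$target <- 10L
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, tmp)
  back <- load_checkpoint(tmp)
  expect_identical(back$params, m$params)
  expect_identical(unclass(back$config), unclass(m$config))
  expect_identical(back$target, 10L)

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "not a model checkpoint")
})

test_that("config invariants are enforced", {
  expect_error(model_config(d_model = 100L, n_heads = 16L), "divisible")
  expect_error(model_config(seq_len = 24L, label_len = 48L),
               "must not exceed")
})
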