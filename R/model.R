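#' Model hyperparameter configuration
#'
#' Defaults follow the completion network's reference settings: embedding
#' dimension 128 with 16 attention heads, a two-layer distilling encoder and
#' a one-layer generative decoder, encoder window length 48 samples, decoder
#' label length 24, four input channels, one output channel, dropout 0.05.
#'
#' @param d_model embedding dimension (divisible by `n_heads`).
#' @param n_heads number of attention heads.
#' @param n_enc_layers encoder layers (a distill block follows each one).
#' @param n_dec_layers decoder layers.
#' @param seq_len encoder input window length L.
#' @param label_len decoder label window length L' (must satisfy L' <= L).
#' @param d_x number of input channels.
#' @param d_y number of output channels (the completion model emits one).
#' @param d_ff feed-forward inner dimension.
#' @param dropout dropout probability used during training.
#' @param sampling_factor ProbSparse top-query control: the number of
#'   queries given full attention is `ceiling(sampling_factor * log(L))`,
#'   capped at L.
#' @param probsparse use ProbSparse attention in the encoder (dense when
#'   `FALSE`).
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed used for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(d_model = 128L, n_heads = 16L, n_enc_layers = 2L,
                         n_dec_layers = 1L, seq_len = 48L, label_len = 24L,
                         d_x = 4L, d_y = 1L, d_ff = 2L * d_model,
                         dropout = 0.05, sampling_factor = 5,
                         probsparse = TRUE, learning_rate = 0.001,
                         seed = 1L) {
  cfg <- list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              n_enc_layers = as.integer(n_enc_layers),
              n_dec_layers = as.integer(n_dec_layers),
              seq_len = as.integer(seq_len),
              label_len = as.integer(label_len),
              d_x = as.integer(d_x), d_y = as.integer(d_y),
              d_ff = as.integer(d_ff), dropout = dropout,
              sampling_factor = sampling_factor,
              probsparse = isTRUE(probsparse),
              learning_rate = learning_rate, seed = as.integer(seed))
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("d_model must be divisible by n_heads", call. = FALSE)
  }
  if (cfg$label_len > cfg$seq_len) {
    stop("label_len must not exceed seq_len", call. = FALSE)
  }
  if (cfg$d_model %% 2L != 0L) stop("d_model must be even", call. = FALSE)
  stopifnot(cfg$d_model > 0, cfg$n_heads > 0, cfg$n_enc_layers > 0,
            cfg$n_dec_layers > 0, cfg$seq_len > 1, cfg$label_len > 0,
            cfg$d_x > 0, cfg$d_y > 0, cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- "model_config"
  cfg
}

#' Initialize an untrained completion model
#'
#' Weights are Glorot-uniform, seeded from `config$seed` so initialization
#' is reproducible.
#'
#' @param config a [model_config()].
#' @return An `ec_informer` object (weights + config).
#' @export
ec_informer <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  structure(list(params = .init_params(config), config = config,
                 norm_params = NULL, inputs = NULL, target = NULL),
            class = "ec_informer")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.ec_informer <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<ec_informer> d_model=%d heads=%d enc=%d dec=%d L=%d L'=%d (%d parameters)\n",
    x$config$d_model, x$config$n_heads, x$config$n_enc_layers,
    x$config$n_dec_layers, x$config$seq_len, x$config$label_len, np))
  if (!is.null(x$inputs)) {
    cat(sprintf("  trained: inputs {%s} -> target %d\n",
                paste(x$inputs, collapse = ","), x$target))
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `ec_informer`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Sinusoidal positional encoding
#'
#' Component `2j` (0-based) is `sin(pos / (2 L_x)^(2j / d_model))` and
#' component `2j + 1` is the cosine of the same argument, pairing indices
#' from j = 0. The base `2 L_x` ties the slowest period to twice the window
#' length, so every position within a window receives a distinct code in
#' \[-1, 1\].
#'
#' @param pos time index (>= 0), possibly a vector.
#' @param L_x window length.
#' @param d_model embedding dimension (even).
#' @return A vector of `d_model` values for scalar `pos`, else a
#'   `length(pos)` x `d_model` matrix.
#' @export
positional_encode <- function(pos, L_x, d_model) {
  stopifnot(all(pos >= 0), d_model %% 2 == 0, L_x > 0)
  P <- .pe_matrix(pos, L_x, d_model)
  if (length(pos) == 1L) drop(P) else P
}

#' Query sparsity measure
#'
#' Scores how far a query's attention distribution is from uniform:
#' `M(q, K) = logsumexp_j(q . k_j / sqrt(d)) - mean_j(q . k_j / sqrt(d))`.
#' M is bounded below by `log(L_K)` (attained when all scores are equal,
#' i.e. a uniform attention row) and grows when the query attends sharply
#' to few keys; queries with the largest M keep full attention under the
#' ProbSparse scheme.
#'
#' @param q query vector of length `d`.
#' @param K key matrix, `L_K` x `d`.
#' @param d head dimension used in the scale factor (defaults to
#'   `length(q)`).
#' @return Scalar M.
#' @export
sparsity_measure <- function(q, K, d = length(q)) {
  K <- as.matrix(K)
  if (nrow(K) == 0L) stop("K must be non-empty", call. = FALSE)
  stopifnot(ncol(K) == length(q))
  s <- as.numeric(K %*% q) / sqrt(d)
  m <- max(s)
  (m + log(sum(exp(s - m)))) - mean(s)
}

#' ProbSparse scaled dot-product attention
#'
#' Single-head attention in which only the `u` queries with the largest
#' sparsity measure receive full softmax attention over all keys; every
#' other query's output row is the mean of the value rows (the "average
#' distribution" fill). The sparsity measure may be estimated from a random
#' subset of `key_sample` keys.
#'
#' @param Q query matrix `L_Q` x `d`.
#' @param K key matrix `L_K` x `d`.
#' @param V value matrix `L_K` x `d_v`.
#' @param u number of queries given full attention; default
#'   `ceiling(5 * log(L_Q))`, capped at `L_Q`. `u = L_Q` reproduces dense
#'   softmax attention, `u = 0` returns the value mean for every query.
#' @param key_sample number of keys used to estimate the sparsity measure;
#'   default (and cap) `L_K`.
#' @return `L_Q` x `d_v` output matrix.
#' @export
probsparse_attention <- function(Q, K, V, u = NULL, key_sample = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    stop("dimension mismatch among Q, K, V", call. = FALSE)
  }
  Lq <- nrow(Q); Lk <- nrow(K); d <- ncol(Q)
  if (is.null(u)) u <- .top_u(Lq, 5)
  u <- min(as.integer(u), Lq)
  if (is.null(key_sample)) key_sample <- Lk
  key_sample <- min(as.integer(key_sample), Lk)
  if (key_sample < 1L) stop("key_sample must be >= 1", call. = FALSE)
  if (u < 0L) stop("u must be >= 0", call. = FALSE)

  vbar <- colMeans(V)
  out <- matrix(rep(vbar, each = Lq), Lq)
  if (u == 0L) return(out)

  ks <- if (key_sample < Lk) sort(sample.int(Lk, key_sample)) else seq_len(Lk)
  M <- vapply(seq_len(Lq), function(i) {
    sparsity_measure(Q[i, ], K[ks, , drop = FALSE], d = d)
  }, numeric(1))
  top <- sort(order(M, decreasing = TRUE)[seq_len(u)])
  S <- Q[top, , drop = FALSE] %*% t(K) / sqrt(d)
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  out[top, ] <- P %*% V
  out
}

#' Self-attention distilling step
#'
#' Applies the sequence-halving operation used between encoder layers:
#' 1-D convolution along time (kernel 3, zero padding 1), ELU activation,
#' then max pooling with kernel 3, stride 2, padding 1. The output length is
#' `ceiling(L / 2)`.
#'
#' @param X an `L` x `d` sequence (L >= 2).
#' @param conv_weights optional list with matrices `W1`, `W2`, `W3`
#'   (`d` x `d`, taps for time offsets -1, 0, +1) and bias vector `b`. The
#'   default is the identity tap (W2 = I, W1 = W3 = 0, b = 0), which reduces
#'   the step to ELU + max pooling.
#' @return A `ceiling(L/2)` x `d` matrix.
#' @export
distill <- function(X, conv_weights = NULL) {
  X <- as.matrix(X)
  L <- nrow(X)
  if (L < 2L) stop("sequence length must be >= 2", call. = FALSE)
  d <- ncol(X)
  if (is.null(conv_weights)) {
    conv_weights <- list(W1 = matrix(0, d, d), W2 = diag(d),
                         W3 = matrix(0, d, d), b = numeric(d))
  }
  cv <- .conv3_fwd(X, conv_weights$W1, conv_weights$W2, conv_weights$W3,
                   conv_weights$b, B = 1L, L = L)
  .maxpool_fwd(.elu(cv$Y), B = 1L, L = L)$Y
}

#' Run the completion network forward
#'
#' Embeds the encoder window and the decoder label window, adds positional
#' codes, runs the distilling encoder stack and the masked/cross-attention
#' decoder, and emits the whole label window in a single pass (no
#' autoregression). Dropout is disabled, so the output is deterministic
#' given weights and inputs.
#'
#' @param model an `ec_informer`.
#' @param enc_in encoder input window, `seq_len` x `d_x`.
#' @param dec_in decoder label window, `label_len` x `d_x`.
#' @param t_s label start offset within the encoder window (default
#'   `seq_len - label_len`, i.e. the trailing part of the window).
#' @return `label_len` x `d_y` output matrix.
#' @export
forward <- function(model, enc_in, dec_in,
                    t_s = model$config$seq_len - model$config$label_len) {
  stopifnot(inherits(model, "ec_informer"))
  cfg <- model$config
  enc_in <- as.matrix(enc_in); dec_in <- as.matrix(dec_in)
  if (!all(is.finite(enc_in)) || !all(is.finite(dec_in))) {
    stop("non-finite values in model input", call. = FALSE)
  }
  if (nrow(enc_in) != cfg$seq_len || ncol(enc_in) != cfg$d_x ||
      nrow(dec_in) != cfg$label_len || ncol(dec_in) != cfg$d_x) {
    stop(sprintf("input shape mismatch: expected %dx%d encoder and %dx%d decoder windows",
                 cfg$seq_len, cfg$d_x, cfg$label_len, cfg$d_x),
         call. = FALSE)
  }
  if (t_s < 0 || t_s + cfg$label_len > cfg$seq_len) {
    stop("t_s violates the label-in-window constraint", call. = FALSE)
  }
  .model_forward(model$params, cfg, enc_in, dec_in, t_s)$Y
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the weights, the model
#' configuration, any stored normalization parameters, the input/target
#' channel ids, and the training seed.
#'
#' @param model an `ec_informer`.
#' @param path file path (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `ec_informer`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ec_informer"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  need <- c("params", "config")
  if (!is.list(obj) || !all(need %in% names(obj))) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  class(obj$config) <- "model_config"
  structure(obj, class = "ec_informer")
}
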