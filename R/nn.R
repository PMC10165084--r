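# Internal neural-network machinery for the completion model.
#
# Batches are processed in stacked form: a batch of B sequences of length L
# with D features is a (B*L) x D matrix, sample b in rows ((b-1)L+1):(bL).
# Pointwise layers (linear, layer norm, ELU, dropout, feed-forward) operate
# directly on the stack with single BLAS calls; attention and pooling use
# per-sample kernels. Backpropagation is hand-derived per layer and checked
# against finite differences in the test suite.

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# --- positional encoding ---------------------------------------------------

.pe_matrix <- function(positions, L_x, d_model) {
  j <- 0:(d_model %/% 2 - 1)
  denom <- (2 * L_x)^(2 * j / d_model)
  ang <- outer(positions, 1 / denom)         # |pos| x d_model/2
  P <- matrix(0, length(positions), d_model)
  P[, 2 * j + 1] <- sin(ang)
  P[, 2 * j + 2] <- cos(ang)
  P
}

# --- layer norm ------------------------------------------------------------

.ln_eps <- 1e-5

.layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + .ln_eps)
  xhat <- xc * inv
  list(Y = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# --- dropout ---------------------------------------------------------------

.dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  q <- 1 - p
  mask <- (matrix(stats::runif(length(X)), nrow(X)) < q) / q
  list(Y = X * mask, mask = mask)
}

.dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# --- ELU -------------------------------------------------------------------

.elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

.elu_grad <- function(x, ex) {                # ex = elu(x)
  g <- array(1, dim(x))
  neg <- x < 0
  g[neg] <- ex[neg] + 1
  g
}

# --- row shifts within stacked samples (for kernel-3 convolution) ----------

.shift_down <- function(X, B, L) {            # row t <- row t-1, zero at t=1
  n <- B * L
  idx <- seq_len(n) - 1L
  first <- (seq_len(n) - 1L) %% L == 0L
  idx[first] <- 1L                            # placeholder, zeroed below
  Y <- X[idx, , drop = FALSE]
  Y[first, ] <- 0
  Y
}

.shift_up <- function(X, B, L) {              # row t <- row t+1, zero at t=L
  n <- B * L
  idx <- seq_len(n) + 1L
  last <- seq_len(n) %% L == 0L
  idx[last] <- 1L
  Y <- X[idx, , drop = FALSE]
  Y[last, ] <- 0
  Y
}

.conv3_fwd <- function(X, W1, W2, W3, b, B, L) {
  Xm <- .shift_down(X, B, L)
  Xp <- .shift_up(X, B, L)
  Y <- Xm %*% W1 + X %*% W2 + Xp %*% W3 + rep(b, each = nrow(X))
  list(Y = Y, Xm = Xm, Xp = Xp)
}

.conv3_bwd <- function(dY, X, cache, W1, W2, W3, B, L) {
  list(dX = .shift_up(dY %*% t(W1), B, L) + dY %*% t(W2) +
         .shift_down(dY %*% t(W3), B, L),
       dW1 = crossprod(cache$Xm, dY),
       dW2 = crossprod(X, dY),
       dW3 = crossprod(cache$Xp, dY),
       db = colSums(dY))
}

# --- max pooling, kernel 3, stride 2, pad 1 --------------------------------

.pool_out_len <- function(L) (L - 1L) %/% 2L + 1L   # == ceil(L/2)

.maxpool_fwd <- function(X, B, L) {
  Lo <- .pool_out_len(L)
  n_out <- B * Lo
  t_out <- rep(seq_len(Lo), B)
  b_out <- rep(seq_len(B), each = Lo)
  gather <- function(k) {                 # input position 2t-2+k, k = 0,1,2
    pos <- 2L * t_out - 2L + k
    ok <- pos >= 1L & pos <= L
    gi <- (b_out - 1L) * L + pmax(pmin(pos, L), 1L)
    G <- X[gi, , drop = FALSE]
    G[!ok, ] <- -Inf
    list(G = G, gi = gi, ok = ok)
  }
  g0 <- gather(0L); g1 <- gather(1L); g2 <- gather(2L)
  Y <- pmax(g0$G, g1$G, g2$G)
  choice <- matrix(2L, n_out, ncol(X))
  choice[Y == g1$G] <- 1L
  choice[Y == g0$G] <- 0L                  # earliest index wins ties
  list(Y = Y, choice = choice,
       gi = list(g0$gi, g1$gi, g2$gi), ok = list(g0$ok, g1$ok, g2$ok))
}

.maxpool_bwd <- function(dY, cache, B, L, D) {
  dX <- matrix(0, B * L, D)
  for (k in 0:2) {
    m <- (cache$choice == k) & cache$ok[[k + 1]]
    contrib <- dY * m
    gi <- cache$gi[[k + 1]]
    keep <- cache$ok[[k + 1]]
    dX[gi[keep], ] <- dX[gi[keep], ] + contrib[keep, , drop = FALSE]
  }
  dX
}

# --- multi-head attention wrapper ------------------------------------------

.top_u <- function(Lq, factor) min(ceiling(factor * log(Lq)), Lq)

.mha_fwd <- function(Xq, Xkv, p, prefix, B, Lq, Lk, H, causal, u, drop_p,
                     train) {
  Q <- Xq %*% p[[paste0(prefix, "_Wq")]] +
    rep(p[[paste0(prefix, "_bq")]], each = nrow(Xq))
  K <- Xkv %*% p[[paste0(prefix, "_Wk")]] +
    rep(p[[paste0(prefix, "_bk")]], each = nrow(Xkv))
  V <- Xkv %*% p[[paste0(prefix, "_Wv")]] +
    rep(p[[paste0(prefix, "_bv")]], each = nrow(Xkv))
  at <- .mha_forward_cpp(Q, K, V, B, Lq, Lk, H, causal, u)
  Op <- at$O %*% p[[paste0(prefix, "_Wo")]] +
    rep(p[[paste0(prefix, "_bo")]], each = nrow(at$O))
  dr <- .dropout_fwd(Op, drop_p, train)
  list(Y = dr$Y, Q = Q, K = K, V = V, O = at$O, P = at$P, sel = at$sel,
       mask = dr$mask)
}

.mha_bwd <- function(dY, cache, Xq, Xkv, p, g, prefix, B, Lq, Lk, H) {
  dOp <- .dropout_bwd(dY, cache$mask)
  dO <- dOp %*% t(p[[paste0(prefix, "_Wo")]])
  g[[paste0(prefix, "_Wo")]] <- g[[paste0(prefix, "_Wo")]] +
    crossprod(cache$O, dOp)
  g[[paste0(prefix, "_bo")]] <- g[[paste0(prefix, "_bo")]] + colSums(dOp)
  bk <- .mha_backward_cpp(dO, cache$Q, cache$K, cache$V, cache$P,
                          cache$sel, B, Lq, Lk, H)
  g[[paste0(prefix, "_Wq")]] <- g[[paste0(prefix, "_Wq")]] +
    crossprod(Xq, bk$dQ)
  g[[paste0(prefix, "_bq")]] <- g[[paste0(prefix, "_bq")]] + colSums(bk$dQ)
  g[[paste0(prefix, "_Wk")]] <- g[[paste0(prefix, "_Wk")]] +
    crossprod(Xkv, bk$dK)
  g[[paste0(prefix, "_bk")]] <- g[[paste0(prefix, "_bk")]] + colSums(bk$dK)
  g[[paste0(prefix, "_Wv")]] <- g[[paste0(prefix, "_Wv")]] +
    crossprod(Xkv, bk$dV)
  g[[paste0(prefix, "_bv")]] <- g[[paste0(prefix, "_bv")]] + colSums(bk$dV)
  dXq <- bk$dQ %*% t(p[[paste0(prefix, "_Wq")]])
  dXkv <- bk$dK %*% t(p[[paste0(prefix, "_Wk")]]) +
    bk$dV %*% t(p[[paste0(prefix, "_Wv")]])
  list(dXq = dXq, dXkv = dXkv, g = g)
}

# --- parameter initialization ----------------------------------------------

.attn_param_names <- function(prefix) {
  paste0(prefix, c("_Wq", "_bq", "_Wk", "_bk", "_Wv", "_bv", "_Wo", "_bo"))
}

.init_params <- function(cfg) {
  D <- cfg$d_model
  dff <- cfg$d_ff
  p <- list()
  lin <- function(nin, nout) .glorot(nin, nout)
  attn <- function(prefix) {
    p[[paste0(prefix, "_Wq")]] <<- lin(D, D)
    p[[paste0(prefix, "_bq")]] <<- numeric(D)
    p[[paste0(prefix, "_Wk")]] <<- lin(D, D)
    p[[paste0(prefix, "_bk")]] <<- numeric(D)
    p[[paste0(prefix, "_Wv")]] <<- lin(D, D)
    p[[paste0(prefix, "_bv")]] <<- numeric(D)
    p[[paste0(prefix, "_Wo")]] <<- lin(D, D)
    p[[paste0(prefix, "_bo")]] <<- numeric(D)
  }
  p$enc_emb_W <- lin(cfg$d_x, D); p$enc_emb_b <- numeric(D)
  p$dec_emb_W <- lin(cfg$d_x, D); p$dec_emb_b <- numeric(D)
  for (l in seq_len(cfg$n_enc_layers)) {
    pre <- paste0("enc", l)
    attn(pre)
    p[[paste0(pre, "_ln1_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln1_b")]] <- numeric(D)
    p[[paste0(pre, "_ff_W1")]] <- lin(D, dff)
    p[[paste0(pre, "_ff_b1")]] <- numeric(dff)
    p[[paste0(pre, "_ff_W2")]] <- lin(dff, D)
    p[[paste0(pre, "_ff_b2")]] <- numeric(D)
    p[[paste0(pre, "_ln2_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln2_b")]] <- numeric(D)
    p[[paste0(pre, "_cv_W1")]] <- lin(D, D)
    p[[paste0(pre, "_cv_W2")]] <- lin(D, D)
    p[[paste0(pre, "_cv_W3")]] <- lin(D, D)
    p[[paste0(pre, "_cv_b")]] <- numeric(D)
  }
  for (l in seq_len(cfg$n_dec_layers)) {
    pre <- paste0("dec", l)
    attn(paste0(pre, "_self"))
    p[[paste0(pre, "_ln1_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln1_b")]] <- numeric(D)
    attn(paste0(pre, "_cross"))
    p[[paste0(pre, "_ln2_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln2_b")]] <- numeric(D)
    p[[paste0(pre, "_ff_W1")]] <- lin(D, dff)
    p[[paste0(pre, "_ff_b1")]] <- numeric(dff)
    p[[paste0(pre, "_ff_W2")]] <- lin(dff, D)
    p[[paste0(pre, "_ff_b2")]] <- numeric(D)
    p[[paste0(pre, "_ln3_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln3_b")]] <- numeric(D)
  }
  # output head: small weights, bias at mid-range of the normalized
  # amplitude domain, so initial predictions start near the data scale
  p$proj_W <- 0.1 * lin(D, cfg$d_y)
  p$proj_b <- rep(0.5, cfg$d_y)
  p
}

# --- residual sublayer helpers ---------------------------------------------

.ffn_fwd <- function(X, p, pre, drop_p, train) {
  Z1 <- X %*% p[[paste0(pre, "_ff_W1")]] +
    rep(p[[paste0(pre, "_ff_b1")]], each = nrow(X))
  A1 <- .elu(Z1)
  Z2 <- A1 %*% p[[paste0(pre, "_ff_W2")]] +
    rep(p[[paste0(pre, "_ff_b2")]], each = nrow(X))
  dr <- .dropout_fwd(Z2, drop_p, train)
  list(Y = dr$Y, Z1 = Z1, A1 = A1, mask = dr$mask)
}

.ffn_bwd <- function(dY, cache, X, p, g, pre) {
  dZ2 <- .dropout_bwd(dY, cache$mask)
  g[[paste0(pre, "_ff_W2")]] <- g[[paste0(pre, "_ff_W2")]] +
    crossprod(cache$A1, dZ2)
  g[[paste0(pre, "_ff_b2")]] <- g[[paste0(pre, "_ff_b2")]] + colSums(dZ2)
  dA1 <- dZ2 %*% t(p[[paste0(pre, "_ff_W2")]])
  dZ1 <- dA1 * .elu_grad(cache$Z1, cache$A1)
  g[[paste0(pre, "_ff_W1")]] <- g[[paste0(pre, "_ff_W1")]] +
    crossprod(X, dZ1)
  g[[paste0(pre, "_ff_b1")]] <- g[[paste0(pre, "_ff_b1")]] + colSums(dZ1)
  list(dX = dZ1 %*% t(p[[paste0(pre, "_ff_W1")]]), g = g)
}

# --- full forward pass ------------------------------------------------------

# Xenc: (B*L) x d_x stacked encoder windows; Xdec: (B*L') x d_x stacked
# decoder label windows; t_s: label start offset (decoder positions are
# t_s .. t_s+L'-1). Returns Y ((B*L') x d_y) and, if keep_cache, every
# intermediate needed by .model_backward.
.model_forward <- function(p, cfg, Xenc, Xdec, t_s, train = FALSE,
                           keep_cache = FALSE) {
  B <- nrow(Xenc) / cfg$seq_len
  stopifnot(B == round(B), nrow(Xdec) == B * cfg$label_len)
  B <- as.integer(B)
  H <- cfg$n_heads
  drop_p <- cfg$dropout
  cache <- list(B = B, Xenc = Xenc, Xdec = Xdec)

  # encoder embedding; value embeddings are scaled by sqrt(d_model) (the
  # usual transformer convention) so the signal dominates the positional
  # code instead of drowning under it
  es <- sqrt(cfg$d_model)
  pe_e <- .pe_matrix(0:(cfg$seq_len - 1), cfg$seq_len, cfg$d_model)
  E0 <- (Xenc %*% p$enc_emb_W) * es + rep(p$enc_emb_b, each = nrow(Xenc)) +
    pe_e[rep(seq_len(cfg$seq_len), B), ]
  dr <- .dropout_fwd(E0, drop_p, train)
  cache$enc_emb_mask <- dr$mask
  X <- dr$Y

  L <- cfg$seq_len
  enc_caches <- vector("list", cfg$n_enc_layers)
  for (l in seq_len(cfg$n_enc_layers)) {
    pre <- paste0("enc", l)
    u <- if (cfg$probsparse) .top_u(L, cfg$sampling_factor) else 0L
    at <- .mha_fwd(X, X, p, pre, B, L, L, H, causal = FALSE, u = u,
                   drop_p = drop_p, train = train)
    R1 <- X + at$Y
    ln1 <- .layernorm_fwd(R1, p[[paste0(pre, "_ln1_g")]],
                          p[[paste0(pre, "_ln1_b")]])
    ff <- .ffn_fwd(ln1$Y, p, pre, drop_p, train)
    R2 <- ln1$Y + ff$Y
    ln2 <- .layernorm_fwd(R2, p[[paste0(pre, "_ln2_g")]],
                          p[[paste0(pre, "_ln2_b")]])
    cv <- .conv3_fwd(ln2$Y, p[[paste0(pre, "_cv_W1")]],
                     p[[paste0(pre, "_cv_W2")]], p[[paste0(pre, "_cv_W3")]],
                     p[[paste0(pre, "_cv_b")]], B, L)
    A <- .elu(cv$Y)
    mp <- .maxpool_fwd(A, B, L)
    enc_caches[[l]] <- list(X_in = X, at = at, ln1 = ln1, ff = ff,
                            ln2 = ln2, cv = cv, A = A, mp = mp, L = L)
    X <- mp$Y
    L <- .pool_out_len(L)
  }
  M <- X                      # encoder memory, (B*Lm) x D
  Lm <- L
  cache$enc <- enc_caches
  cache$Lm <- Lm
  cache$M <- M

  # decoder embedding at label positions
  pe_d <- .pe_matrix(t_s:(t_s + cfg$label_len - 1), cfg$seq_len, cfg$d_model)
  D0 <- (Xdec %*% p$dec_emb_W) * es + rep(p$dec_emb_b, each = nrow(Xdec)) +
    pe_d[rep(seq_len(cfg$label_len), B), ]
  dr <- .dropout_fwd(D0, drop_p, train)
  cache$dec_emb_mask <- dr$mask
  Xd <- dr$Y
  Lp <- cfg$label_len

  dec_caches <- vector("list", cfg$n_dec_layers)
  for (l in seq_len(cfg$n_dec_layers)) {
    pre <- paste0("dec", l)
    at1 <- .mha_fwd(Xd, Xd, p, paste0(pre, "_self"), B, Lp, Lp, H,
                    causal = TRUE, u = 0L, drop_p = drop_p, train = train)
    R1 <- Xd + at1$Y
    ln1 <- .layernorm_fwd(R1, p[[paste0(pre, "_ln1_g")]],
                          p[[paste0(pre, "_ln1_b")]])
    at2 <- .mha_fwd(ln1$Y, M, p, paste0(pre, "_cross"), B, Lp, Lm, H,
                    causal = FALSE, u = 0L, drop_p = drop_p, train = train)
    R2 <- ln1$Y + at2$Y
    ln2 <- .layernorm_fwd(R2, p[[paste0(pre, "_ln2_g")]],
                          p[[paste0(pre, "_ln2_b")]])
    ff <- .ffn_fwd(ln2$Y, p, pre, drop_p, train)
    R3 <- ln2$Y + ff$Y
    ln3 <- .layernorm_fwd(R3, p[[paste0(pre, "_ln3_g")]],
                          p[[paste0(pre, "_ln3_b")]])
    dec_caches[[l]] <- list(X_in = Xd, at1 = at1, ln1 = ln1, at2 = at2,
                            ln2 = ln2, ff = ff, ln3 = ln3)
    Xd <- ln3$Y
  }
  cache$dec <- dec_caches
  cache$dec_out <- Xd

  Y <- Xd %*% p$proj_W + rep(p$proj_b, each = nrow(Xd))
  if (keep_cache) list(Y = Y, cache = cache) else list(Y = Y)
}

# Backward pass: dY is the gradient of the loss w.r.t. the output stack.
# Returns a named list of parameter gradients (same shapes as p).
.model_backward <- function(p, cfg, cache, dY) {
  B <- cache$B
  H <- cfg$n_heads
  Lp <- cfg$label_len
  Lm <- cache$Lm
  g <- lapply(p, function(w) array(0, dim = dim(w) %||% length(w)))
  g <- lapply(g, function(w) if (is.matrix(w)) w else as.numeric(w))
  names(g) <- names(p)

  g$proj_W <- crossprod(cache$dec_out, dY)
  g$proj_b <- colSums(dY)
  dXd <- dY %*% t(p$proj_W)
  dM <- matrix(0, nrow = B * Lm, ncol = cfg$d_model)

  for (l in rev(seq_len(cfg$n_dec_layers))) {
    pre <- paste0("dec", l)
    cc <- cache$dec[[l]]
    b3 <- .layernorm_bwd(dXd, cc$ln3, p[[paste0(pre, "_ln3_g")]])
    g[[paste0(pre, "_ln3_g")]] <- g[[paste0(pre, "_ln3_g")]] + b3$dg
    g[[paste0(pre, "_ln3_b")]] <- g[[paste0(pre, "_ln3_b")]] + b3$db
    dR3 <- b3$dX
    fb <- .ffn_bwd(dR3, cc$ff, cc$ln2$Y, p, g, pre)
    g <- fb$g
    dN2 <- dR3 + fb$dX
    b2 <- .layernorm_bwd(dN2, cc$ln2, p[[paste0(pre, "_ln2_g")]])
    g[[paste0(pre, "_ln2_g")]] <- g[[paste0(pre, "_ln2_g")]] + b2$dg
    g[[paste0(pre, "_ln2_b")]] <- g[[paste0(pre, "_ln2_b")]] + b2$db
    dR2 <- b2$dX
    ab2 <- .mha_bwd(dR2, cc$at2, cc$ln1$Y, cache$M, p, g,
                    paste0(pre, "_cross"), B, Lp, Lm, H)
    g <- ab2$g
    dM <- dM + ab2$dXkv
    dN1 <- dR2 + ab2$dXq
    b1 <- .layernorm_bwd(dN1, cc$ln1, p[[paste0(pre, "_ln1_g")]])
    g[[paste0(pre, "_ln1_g")]] <- g[[paste0(pre, "_ln1_g")]] + b1$dg
    g[[paste0(pre, "_ln1_b")]] <- g[[paste0(pre, "_ln1_b")]] + b1$db
    dR1 <- b1$dX
    ab1 <- .mha_bwd(dR1, cc$at1, cc$X_in, cc$X_in, p, g,
                    paste0(pre, "_self"), B, Lp, Lp, H)
    g <- ab1$g
    dXd <- dR1 + ab1$dXq + ab1$dXkv
  }

  # decoder embedding (input windows are data: no gradient flows past it)
  es <- sqrt(cfg$d_model)
  dD0 <- .dropout_bwd(dXd, cache$dec_emb_mask)
  g$dec_emb_b <- g$dec_emb_b + colSums(dD0)
  g$dec_emb_W <- g$dec_emb_W + crossprod(cache$Xdec, dD0) * es

  # encoder stack
  dX <- dM
  for (l in rev(seq_len(cfg$n_enc_layers))) {
    pre <- paste0("enc", l)
    cc <- cache$enc[[l]]
    L <- cc$L
    dA <- .maxpool_bwd(dX, cc$mp, B, L, cfg$d_model)
    dC <- dA * .elu_grad(cc$cv$Y, cc$A)
    cb <- .conv3_bwd(dC, cc$ln2$Y, cc$cv, p[[paste0(pre, "_cv_W1")]],
                     p[[paste0(pre, "_cv_W2")]], p[[paste0(pre, "_cv_W3")]],
                     B, L)
    g[[paste0(pre, "_cv_W1")]] <- g[[paste0(pre, "_cv_W1")]] + cb$dW1
    g[[paste0(pre, "_cv_W2")]] <- g[[paste0(pre, "_cv_W2")]] + cb$dW2
    g[[paste0(pre, "_cv_W3")]] <- g[[paste0(pre, "_cv_W3")]] + cb$dW3
    g[[paste0(pre, "_cv_b")]] <- g[[paste0(pre, "_cv_b")]] + cb$db
    dN2 <- cb$dX
    b2 <- .layernorm_bwd(dN2, cc$ln2, p[[paste0(pre, "_ln2_g")]])
    g[[paste0(pre, "_ln2_g")]] <- g[[paste0(pre, "_ln2_g")]] + b2$dg
    g[[paste0(pre, "_ln2_b")]] <- g[[paste0(pre, "_ln2_b")]] + b2$db
    dR2 <- b2$dX
    fb <- .ffn_bwd(dR2, cc$ff, cc$ln1$Y, p, g, pre)
    g <- fb$g
    dN1 <- dR2 + fb$dX
    b1 <- .layernorm_bwd(dN1, cc$ln1, p[[paste0(pre, "_ln1_g")]])
    g[[paste0(pre, "_ln1_g")]] <- g[[paste0(pre, "_ln1_g")]] + b1$dg
    g[[paste0(pre, "_ln1_b")]] <- g[[paste0(pre, "_ln1_b")]] + b1$db
    dR1 <- b1$dX
    ab <- .mha_bwd(dR1, cc$at, cc$X_in, cc$X_in, p, g, pre, B, L, L, H)
    g <- ab$g
    dX <- dR1 + ab$dXq + ab$dXkv
  }

  dE0 <- .dropout_bwd(dX, cache$enc_emb_mask)
  g$enc_emb_b <- g$enc_emb_b + colSums(dE0)
  g$enc_emb_W <- g$enc_emb_W + crossprod(cache$Xenc, dE0) * es
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Adam -------------------------------------------------------------------

.adam_init <- function(p) {
  list(m = lapply(p, function(w) w * 0), v = lapply(p, function(w) w * 0),
       t = 0L)
}

.adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in names(p)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g[[k]]^2
    p[[k]] <- p[[k]] - lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  list(p = p, state = st)
}
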