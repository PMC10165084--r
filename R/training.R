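#' Windowing specification
#'
#' Defines how a recording is cut into training/inference windows: an
#' encoder window of `L` samples, a decoder label window of `L_prime`
#' samples starting `t_s` samples into the encoder window, and a hop of
#' `stride` samples between consecutive windows. The label window must lie
#' entirely inside the encoder window (`t_s >= 0`,
#' `t_s + L_prime <= L`), so the completed channel's label positions are
#' always covered by input-channel context on both sides.
#'
#' @param L encoder window length (default 48).
#' @param L_prime label window length (default 24).
#' @param t_s label start offset; default `L - L_prime` (the trailing part
#'   of the window, i.e. the label start is shifted backward).
#' @param stride hop between window starts (default `L_prime`).
#' @return A `window_spec` list.
#' @export
window_spec <- function(L = 48L, L_prime = 24L, t_s = L - L_prime,
                        stride = L_prime) {
  L <- as.integer(L); L_prime <- as.integer(L_prime)
  t_s <- as.integer(t_s); stride <- as.integer(stride)
  if (L < 1L || L_prime < 1L || stride < 1L) {
    stop("L, L_prime and stride must be positive", call. = FALSE)
  }
  if (t_s < 0L || t_s + L_prime - 1L > L - 1L) {
    stop("label window must lie inside the encoder window: need t_s >= 0 and t_s + L_prime - 1 <= L - 1",
         call. = FALSE)
  }
  structure(list(L = L, L_prime = L_prime, t_s = t_s, stride = stride),
            class = "window_spec")
}

#' Cut a recording into windowed training samples
#'
#' Each sample holds the encoder input (the `L` x `n_inputs` slice of the
#' input channels), the decoder input (the `L_prime` x `n_inputs` slice of
#' the same channels starting at `t_s`), the label (the `L_prime` x 1
#' verbatim slice of the target channel over the same span) and the window's
#' start index. Windows tile the recording at `spec$stride`; a trailing
#' partial window is dropped.
#'
#' @param rec a normalized `eeg_recording` containing the input channels
#'   and (for supervised training) the target channel.
#' @param inputs input channel ids.
#' @param target target channel id (must not be an input).
#' @param spec a [window_spec()].
#' @return A list of class `windowed_samples`.
#' @export
make_windows <- function(rec, inputs, target, spec = window_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "window_spec"))
  if (target %in% inputs) {
    stop("target channel must not be an input channel", call. = FALSE)
  }
  n <- ncol(rec$data)
  if (n < spec$L) {
    stop(sprintf("recording too short for windowing (%d < L = %d)",
                 n, spec$L), call. = FALSE)
  }
  Xin <- t(rec$data[match(as.integer(inputs), rec$channel_ids), ,
                    drop = FALSE])
  if (anyNA(Xin)) stop("input channel(s) not in recording", call. = FALSE)
  y <- channel_signal(rec, target)
  starts <- seq.int(1L, n - spec$L + 1L, by = spec$stride)
  samples <- lapply(starts, function(s) {
    lab0 <- s + spec$t_s
    list(enc = Xin[s:(s + spec$L - 1L), , drop = FALSE],
         dec = Xin[lab0:(lab0 + spec$L_prime - 1L), , drop = FALSE],
         label = matrix(y[lab0:(lab0 + spec$L_prime - 1L)], ncol = 1L),
         start = s)
  })
  structure(list(samples = samples, inputs = as.integer(inputs),
                 target = as.integer(target), spec = spec, n_samples = n),
            class = "windowed_samples")
}

#' @export
length.windowed_samples <- function(x) length(x$samples)

.stack_windows <- function(samples, what) {
  do.call(rbind, lapply(samples, `[[`, what))
}

#' Training run settings
#'
#' @param epochs passes over the training windows. The reference setting is
#'   3; `preset = "satisfactory"` selects the longer 15-epoch schedule used
#'   by the experiment harnesses.
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param seed seed controlling shuffling and dropout.
#' @param shuffle shuffle windows each epoch.
#' @param preset `"reference"` (3 epochs) or `"satisfactory"` (15 epochs);
#'   overrides `epochs` when given.
#' @param verbose print per-epoch loss.
#' @return A `training_run` list.
#' @export
training_run <- function(epochs = 3L, batch_size = 128L,
                         learning_rate = 0.001, seed = 1L, shuffle = TRUE,
                         preset = NULL, verbose = FALSE) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("reference", "satisfactory"))
    epochs <- if (preset == "satisfactory") 15L else 3L
  }
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), verbose = isTRUE(verbose),
                 loss_history = numeric(0)),
            class = "training_run")
}

#' Train the completion model on windowed samples
#'
#' Minimizes the mean squared error between the network output and the
#' target-channel label windows with Adam. Weight initialization, shuffling
#' and dropout are all driven by the seeds in `model$config` and `run`, so
#' two identical calls produce identical loss histories and weights.
#'
#' @param samples a `windowed_samples` object from [make_windows()].
#' @param config a [model_config()] (ignored when `model` is supplied).
#' @param run a [training_run()].
#' @param model optionally a pre-initialized or pre-trained `ec_informer`
#'   to continue training.
#' @return A list with `model` (trained) and `run` (with per-epoch mean MSE
#'   in `run$loss_history`).
#' @export
train_model <- function(samples, config = model_config(),
                        run = training_run(), model = NULL) {
  stopifnot(inherits(samples, "windowed_samples"),
            inherits(run, "training_run"))
  if (length(samples) == 0L) stop("no training windows", call. = FALSE)
  if (is.null(model)) model <- ec_informer(config)
  cfg <- model$config
  spec <- samples$spec
  if (spec$L != cfg$seq_len || spec$L_prime != cfg$label_len) {
    stop("window spec does not match the model configuration", call. = FALSE)
  }
  if (ncol(samples$samples[[1]]$enc) != cfg$d_x) {
    stop(sprintf("model expects %d input channels, got %d", cfg$d_x,
                 ncol(samples$samples[[1]]$enc)), call. = FALSE)
  }

  p <- model$params
  st <- .adam_init(p)
  ns <- length(samples)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(run$seed)
  losses <- numeric(run$epochs)
  for (ep in seq_len(run$epochs)) {
    ord <- if (run$shuffle) sample.int(ns) else seq_len(ns)
    ep_loss <- 0
    n_seen <- 0L
    for (b0 in seq.int(1L, ns, by = run$batch_size)) {
      idx <- ord[b0:min(b0 + run$batch_size - 1L, ns)]
      batch <- samples$samples[idx]
      Xenc <- .stack_windows(batch, "enc")
      Xdec <- .stack_windows(batch, "dec")
      Yt <- .stack_windows(batch, "label")
      fw <- .model_forward(p, cfg, Xenc, Xdec, spec$t_s, train = TRUE,
                           keep_cache = TRUE)
      err <- fw$Y - Yt
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d", ep),
             call. = FALSE)
      }
      g <- .model_backward(p, cfg, fw$cache, 2 * err / length(err))
      up <- .adam_step(p, g, st, run$learning_rate)
      p <- up$p
      st <- up$state
      ep_loss <- ep_loss + loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    losses[ep] <- ep_loss / n_seen
    if (run$verbose) {
      message(sprintf("epoch %d/%d  mean MSE %.6f", ep, run$epochs,
                      losses[ep]))
    }
  }
  model$params <- p
  model$inputs <- samples$inputs
  model$target <- samples$target
  run$loss_history <- losses
  list(model = model, run = run)
}

#' Complete a channel across a whole recording
#'
#' Slides windows over the recording, predicts each label window with the
#' trained model, and averages overlapping predictions per time point to
#' produce the complementary signal for the target channel. Head and tail
#' samples not covered by any label window (at most `L - 1` positions)
#' are filled with the nearest predicted value.
#'
#' @param model a trained `ec_informer`.
#' @param rec a normalized `eeg_recording` containing the model's input
#'   channels (the target channel need not be present).
#' @param inputs input channel ids; defaults to the ids the model was
#'   trained on.
#' @param stride hop between inference windows; default `label_len / 2`
#'   for smoother stitching.
#' @param batch_size windows evaluated per forward pass.
#' @return A one-channel `eeg_recording` (the complementary signal), same
#'   length and rate as `rec`, carrying the target channel id.
#' @export
complete_channel <- function(model, rec, inputs = model$inputs,
                             stride = max(1L, model$config$label_len %/% 2L),
                             batch_size = 256L) {
  stopifnot(inherits(model, "ec_informer"), inherits(rec, "eeg_recording"))
  cfg <- model$config
  if (is.null(inputs)) stop("input channel ids required", call. = FALSE)
  if (length(inputs) != cfg$d_x) {
    stop(sprintf("model expects %d input channels", cfg$d_x), call. = FALSE)
  }
  ii <- match(as.integer(inputs), rec$channel_ids)
  if (anyNA(ii)) stop("input channel(s) not in recording", call. = FALSE)
  Xin <- t(rec$data[ii, , drop = FALSE])
  n <- nrow(Xin)
  L <- cfg$seq_len
  Lp <- cfg$label_len
  t_s <- L - Lp
  if (n < L) stop("recording shorter than one window", call. = FALSE)

  starts <- unique(c(seq.int(1L, n - L + 1L, by = stride), n - L + 1L))
  acc <- numeric(n)
  cnt <- numeric(n)
  for (c0 in seq.int(1L, length(starts), by = batch_size)) {
    ss <- starts[c0:min(c0 + batch_size - 1L, length(starts))]
    Xenc <- do.call(rbind, lapply(ss, function(s) {
      Xin[s:(s + L - 1L), , drop = FALSE]
    }))
    Xdec <- do.call(rbind, lapply(ss, function(s) {
      Xin[(s + t_s):(s + t_s + Lp - 1L), , drop = FALSE]
    }))
    Y <- .model_forward(model$params, cfg, Xenc, Xdec, t_s)$Y
    for (k in seq_along(ss)) {
      pos <- (ss[k] + t_s):(ss[k] + t_s + Lp - 1L)
      acc[pos] <- acc[pos] + Y[((k - 1L) * Lp + 1L):(k * Lp), 1L]
      cnt[pos] <- cnt[pos] + 1
    }
  }
  covered <- cnt > 0
  out <- numeric(n)
  out[covered] <- acc[covered] / cnt[covered]
  if (!all(covered)) {
    ic <- which(covered)
    for (i in which(!covered)) out[i] <- out[ic[which.min(abs(ic - i))]]
  }
  target_id <- model$target %||% (max(rec$channel_ids) + 1L)
  state <- if (min(out) >= -1e-9 && max(out) <= 1 + 1e-9) "normalized"
           else "filtered"   # network output is unconstrained at the edges
  recording(matrix(out, nrow = 1L), rate = rec$rate,
            channel_ids = target_id, units_state = state)
}
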