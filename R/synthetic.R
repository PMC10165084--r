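#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the data regime the completion model is built
#' for: 22 channels on a 2.5 cm planar grid sampled at 250 Hz, with signal
#' content confined to the 2--40 Hz band. Latent band-limited oscillators
#' ("sources") sit at grid nodes; each electrode observes a
#' distance-attenuated Gaussian mixture of the sources plus independent
#' noise, a deliberately simple stand-in for volume conduction (no head
#' model).
#'
#' @param n_sources number of latent oscillators.
#' @param bands list of `c(low, high)` Hz pairs within 2--40; sources cycle
#'   through them. Defaults to the theta, alpha and beta rhythms plus a
#'   broadband component.
#' @param duration_s recording length in seconds.
#' @param rate sampling rate in Hz (must exceed twice the highest band
#'   edge).
#' @param spatial_decay length scale (cm) of the Gaussian source-to-
#'   electrode attenuation kernel.
#' @param noise_sd per-channel additive white-noise level, as a fraction of
#'   that channel's signal standard deviation.
#' @param nonlinearity `"none"` or `"mild"` (a tanh squash of each
#'   electrode's mixture, so the target is not an exactly linear function
#'   of its neighbors).
#' @param source_channels optional fixed channel ids at whose grid nodes
#'   the sources sit (recycled); by default nodes are drawn at random.
#' @param seed RNG seed; everything the generator draws derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sources = 8L,
                             bands = list(c(4, 8), c(8, 13), c(14, 30),
                                          c(2, 40)),
                             duration_s = 60, rate = 250,
                             spatial_decay = 4, noise_sd = 0.05,
                             nonlinearity = c("none", "mild"),
                             source_channels = NULL, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_sources >= 1L, duration_s > 0, rate > 0, spatial_decay > 0,
            noise_sd >= 0)
  for (b in bands) {
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2]) {
      stop("each band must be c(low, high) with 0 < low < high",
           call. = FALSE)
    }
    if (rate <= 2 * b[2]) {
      stop(sprintf("rate %g cannot represent band edge %g Hz", rate, b[2]),
           call. = FALSE)
    }
  }
  structure(list(n_sources = as.integer(n_sources), bands = bands,
                 duration_s = duration_s, rate = rate,
                 spatial_decay = spatial_decay, noise_sd = noise_sd,
                 nonlinearity = nonlinearity,
                 source_channels = source_channels,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# 1/f-amplitude noise restricted to [f_lo, f_hi], unit variance
.pink_band <- function(n, rate, f_lo = 1, f_hi = 45) {
  freq <- seq(0, rate / 2, length.out = n %/% 2 + 1)
  amp <- ifelse(freq >= f_lo & freq <= f_hi, 1 / sqrt(freq), 0)
  phase <- stats::runif(length(freq), 0, 2 * pi)
  half <- amp * exp(1i * phase)
  half[1] <- 0
  spec <- c(half, Conj(rev(half[2:(n - length(half) + 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x[seq_len(n)]))
}

.bandlimited_source <- function(n, rate, band) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * rate))
  x <- x[(rate + 1):(rate + n)]              # drop filter warm-up margins
  as.numeric(scale(x))
}

.draw_sources <- function(layout, cfg) {
  ids <- if (is.null(cfg$source_channels)) {
    sample(layout$channel, cfg$n_sources,
           replace = cfg$n_sources > nrow(layout))
  } else {
    rep_len(as.integer(cfg$source_channels), cfg$n_sources)
  }
  bands <- cfg$bands[((seq_len(cfg$n_sources) - 1L) %% length(cfg$bands)) + 1L]
  pos <- .layout_coords(layout, ids)
  list(channel = ids, band = bands, x_cm = pos[, 1], y_cm = pos[, 2])
}

.mixing_matrix <- function(elec_xy, src, spatial_decay) {
  dx <- outer(elec_xy[, 1], src$x_cm, "-")
  dy <- outer(elec_xy[, 2], src$y_cm, "-")
  exp(-(dx^2 + dy^2) / (2 * spatial_decay^2))
}

.render_session <- function(src, elec_xy, channel_ids, cfg) {
  n <- round(cfg$duration_s * cfg$rate)
  S <- vapply(seq_along(src$channel), function(s) {
    osc <- .bandlimited_source(n, cfg$rate, src$band[[s]])
    bg <- .pink_band(n, cfg$rate)
    as.numeric(scale(osc + 0.3 * bg))
  }, numeric(n))                              # n x n_sources
  A <- .mixing_matrix(elec_xy, src, cfg$spatial_decay)
  X <- A %*% t(S)                             # channels x samples
  if (cfg$nonlinearity == "mild") {
    sc <- apply(X, 1, stats::sd)
    X <- sc * tanh(X / sc)
  }
  if (cfg$noise_sd > 0) {
    sc <- apply(X, 1, stats::sd)
    X <- X + matrix(stats::rnorm(length(X)), nrow(X)) * cfg$noise_sd * sc
  }
  list(rec = recording(X, rate = cfg$rate, channel_ids = channel_ids,
                       units_state = "raw"),
       mixing = A)
}

#' Generate a synthetic multichannel EEG-like recording
#'
#' Latent sources are band-limited stochastic oscillations with a pink
#' (1/f) background; each electrode observes a Gaussian distance-weighted
#' mixture plus independent white noise. Fully reproducible from
#' `cfg$seed`.
#'
#' @param layout an `electrode_layout` (default the bundled 22-channel
#'   grid).
#' @param cfg a [synthetic_config()].
#' @return A list with `rec` (the `eeg_recording`), `mixing` (the
#'   channels x sources attenuation matrix) and `sources` (node ids, bands
#'   and coordinates of the latent oscillators).
#' @export
generate_recording <- function(layout = build_2a_layout(),
                               cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  src <- .draw_sources(layout, cfg)
  out <- .render_session(src, cbind(layout$x_cm, layout$y_cm),
                         layout$channel, cfg)
  list(rec = out$rec, mixing = out$mixing, sources = src)
}

#' Generate a training/test session pair for one synthetic subject
#'
#' Both sessions share the same latent-source structure (node positions and
#' bands) but draw independent source trajectories and noise, emulating two
#' acquisition sessions of the same subject. `session_jitter` displaces
#' every electrode of the test session by that fraction of the 2.5 cm grid
#' pitch in a random direction, emulating a change in cap placement between
#' acquisitions.
#'
#' @param layout an `electrode_layout`.
#' @param cfg a [synthetic_config()].
#' @param session_jitter electrode displacement as a fraction of the grid
#'   pitch, in `[0, 0.5)`.
#' @return A list with `train`, `test` (recordings), `mixing_train`,
#'   `mixing_test`, and `sources`.
#' @export
generate_subject_pair <- function(layout = build_2a_layout(),
                                  cfg = synthetic_config(),
                                  session_jitter = 0) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (session_jitter < 0 || session_jitter >= 0.5) {
    stop("session_jitter must lie in [0, 0.5)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  src <- .draw_sources(layout, cfg)
  xy <- cbind(layout$x_cm, layout$y_cm)
  theta <- stats::runif(nrow(xy), 0, 2 * pi)
  xy_test <- xy + session_jitter * 2.5 * cbind(cos(theta), sin(theta))
  train <- .render_session(src, xy, layout$channel, cfg)
  test <- .render_session(src, xy_test, layout$channel, cfg)
  list(train = train$rec, test = test$rec,
       mixing_train = train$mixing, mixing_test = test$mixing,
       sources = src)
}

#' Write the ground-truth mixing description as a plain-text table
#'
#' @param sim result of [generate_recording()].
#' @param path output path (tab-separated; one row per channel x source
#'   pair).
#' @return `path`, invisibly.
#' @export
write_mixing_table <- function(sim, path) {
  A <- sim$mixing
  tab <- data.frame(
    channel = rep(seq_len(nrow(A)), ncol(A)),
    source = rep(seq_len(ncol(A)), each = nrow(A)),
    source_node = rep(sim$sources$channel, each = nrow(A)),
    weight = as.numeric(A))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
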