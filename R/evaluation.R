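.as_signal <- function(x) {
  if (inherits(x, "eeg_recording")) {
    if (nrow(x$data) != 1L) {
      stop("expected a single-channel signal", call. = FALSE)
    }
    as.numeric(x$data[1L, ])
  } else {
    as.numeric(x)
  }
}

#' Mean squared error between two signals
#'
#' `E = mean((P - P_hat)^2)` over the common window. Reported on whatever
#' scale the signals are in; the package's evaluation harnesses use the
#' normalized \[0, 1\] scale.
#'
#' @param P,P_hat equal-length numeric vectors (or one-channel recordings).
#' @return Scalar E >= 0.
#' @export
mse <- function(P, P_hat) {
  P <- .as_signal(P); P_hat <- .as_signal(P_hat)
  if (length(P) == 0L) stop("empty signals", call. = FALSE)
  if (length(P) != length(P_hat)) {
    stop("signals must have equal length", call. = FALSE)
  }
  mean((P - P_hat)^2)
}

#' Pearson correlation between two signals
#'
#' The product-moment correlation of the original and the complementary
#' signal: 1 means the complementary signal retains the original's course
#' exactly (up to a positive affine map), 0 means the signals are
#' unrelated.
#'
#' @param P,P_hat equal-length numeric vectors (length >= 2, both
#'   non-constant).
#' @return rho in \[-1, 1\].
#' @export
pearson_rho <- function(P, P_hat) {
  P <- .as_signal(P); P_hat <- .as_signal(P_hat)
  if (length(P) != length(P_hat)) {
    stop("signals must have equal length", call. = FALSE)
  }
  if (length(P) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(P) <= .Machine$double.eps ||
      stats::sd(P_hat) <= .Machine$double.eps) {
    stop("correlation undefined for a constant signal", call. = FALSE)
  }
  stats::cor(P, P_hat)
}

#' Baseline correction (mean removal)
#'
#' Sets the signal's mean to zero so that measured and synthesized channels
#' share a common reference. Correlations against any other signal are
#' unchanged.
#'
#' @param sig numeric vector (or one-channel recording).
#' @return Zero-mean numeric vector of the same length.
#' @export
baseline_correct <- function(sig) {
  sig <- .as_signal(sig)
  if (length(sig) == 0L) stop("empty signal", call. = FALSE)
  sig - mean(sig)
}

#' Amplitude correction coefficient
#'
#' Rescales a complementary signal so its total absolute amplitude matches
#' the reference: `alpha = sum(|P|) / sum(|P_hat|)`, corrected signal
#' `alpha * P_hat`. Useful for edge electrodes whose synthesized amplitude
#' is systematically low or high while the waveform course is right.
#'
#' @param P reference signal.
#' @param P_hat signal to rescale (must not be all zero).
#' @return List with `alpha` and `corrected`.
#' @export
amplitude_correct <- function(P, P_hat) {
  P <- .as_signal(P); P_hat <- .as_signal(P_hat)
  if (length(P) != length(P_hat)) {
    stop("signals must have equal length", call. = FALSE)
  }
  denom <- sum(abs(P_hat))
  if (denom <= .Machine$double.eps) {
    stop("amplitude correction undefined for an all-zero signal",
         call. = FALSE)
  }
  alpha <- sum(abs(P)) / denom
  list(alpha = alpha, corrected = alpha * P_hat)
}

#' Inverse-distance interpolation of a target channel
#'
#' The spatial-interpolation baseline: the target channel is estimated as a
#' weighted sum of the input channels, with weights proportional to the
#' inverse distance between each input electrode and the target electrode,
#' `eta_i = (1/d_i) / sum_l(1/d_l)`. Weights are positive, sum to one, and
#' decrease with distance.
#'
#' @param rec an `eeg_recording` containing the input channels.
#' @param layout an `electrode_layout` with all involved electrodes.
#' @param inputs input channel ids.
#' @param target target channel id (must not coincide with an input).
#' @return List with `signal` (numeric vector) and `weights` (a data.frame
#'   with `channel`, `distance_cm`, `eta`).
#' @export
interpolate_channel <- function(rec, layout, inputs, target) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target %in% inputs) {
    stop("target must not be an input channel", call. = FALSE)
  }
  d <- vapply(inputs, function(a) pairwise_distance(layout, a, target),
              numeric(1))
  if (any(d <= .Machine$double.eps)) {
    stop("input electrode coincides with the target electrode",
         call. = FALSE)
  }
  eta <- (1 / d) / sum(1 / d)
  X <- rec$data[match(as.integer(inputs), rec$channel_ids), , drop = FALSE]
  if (anyNA(X)) stop("input channel(s) not in recording", call. = FALSE)
  list(signal = as.numeric(crossprod(X, eta)),
       weights = data.frame(channel = as.integer(inputs),
                            distance_cm = d, eta = eta))
}

#' Flag a possibly damaged channel
#'
#' Compares a measured channel against its model-synthesized complementary
#' signal. The channel is flagged when the correlation falls below
#' `rho_threshold`, or (optionally) when the baseline-corrected MSE exceeds
#' `mse_factor` times a historical reference MSE for that channel. A
#' damaged or interference-laden electrode loses correlation with the
#' signal reconstructed from its neighbors.
#'
#' @param measured the measured channel signal.
#' @param complementary the model-synthesized signal for the same channel.
#' @param rho_threshold correlation threshold in (0, 1); default 0.5.
#' @param reference_mse optional historical baseline-corrected MSE.
#' @param mse_factor multiple of `reference_mse` above which the channel is
#'   flagged (default 3).
#' @return List with `flagged` (logical), `rho`, `mse` (baseline-corrected)
#'   and the thresholds used.
#' @export
flag_bad_channel <- function(measured, complementary, rho_threshold = 0.5,
                             reference_mse = NULL, mse_factor = 3) {
  if (rho_threshold <= 0 || rho_threshold >= 1) {
    stop("rho_threshold must lie in (0, 1)", call. = FALSE)
  }
  measured <- .as_signal(measured)
  complementary <- .as_signal(complementary)
  rho <- pearson_rho(measured, complementary)
  e <- mse(baseline_correct(measured), baseline_correct(complementary))
  flagged <- rho < rho_threshold
  if (!is.null(reference_mse)) {
    flagged <- flagged || e > mse_factor * reference_mse
  }
  list(flagged = flagged, rho = rho, mse = e,
       rho_threshold = rho_threshold,
       reference_mse = reference_mse, mse_factor = mse_factor)
}

#' Evaluate a completed channel against the truth
#'
#' Applies the requested corrections (baseline, then amplitude) to the
#' complementary signal and reports the error and agreement metrics in one
#' record. Baseline correction, when requested, is applied to both signals
#' so they share a zero reference.
#'
#' @param true_target the measured target-channel signal.
#' @param complementary the synthesized signal.
#' @param baseline apply baseline correction (default TRUE).
#' @param amplitude apply amplitude correction (default FALSE).
#' @return A `completion_metrics` list: `mse_raw`, `mse` (after
#'   corrections), `rho`, `alpha` (1 when amplitude correction is off) and
#'   `corrections_applied`.
#' @export
evaluate_completion <- function(true_target, complementary,
                                baseline = TRUE, amplitude = FALSE) {
  P <- .as_signal(true_target)
  Ph <- .as_signal(complementary)
  e_raw <- mse(P, Ph)
  rho <- pearson_rho(P, Ph)
  alpha <- 1
  if (baseline) {
    P <- baseline_correct(P)
    Ph <- baseline_correct(Ph)
  }
  if (amplitude) {
    ac <- amplitude_correct(P, Ph)
    alpha <- ac$alpha
    Ph <- ac$corrected
  }
  structure(list(mse_raw = e_raw, mse = mse(P, Ph), rho = rho,
                 alpha = alpha,
                 corrections_applied = c(baseline = baseline,
                                         amplitude = amplitude)),
            class = "completion_metrics")
}

#' @export
print.completion_metrics <- function(x, ...) {
  cat(sprintf("<completion_metrics> MSE %.3g (raw %.3g)  rho %.4f  alpha %.3f\n",
              x$mse, x$mse_raw, x$rho, x$alpha))
  invisible(x)
}
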