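#' Band-pass filter a recording
#'
#' EEG information of interest lives in roughly the 2--40 Hz band; power-line
#' interference and high-frequency noise are removed by band-pass filtering
#' before any modeling. The filter is a 4th-order Butterworth applied
#' forward and backward ([signal::filtfilt()]), i.e. zero-phase, so channels
#' stay time-aligned.
#'
#' @param rec an `eeg_recording`.
#' @param low,high passband edges in Hz; must satisfy
#'   `0 < low < high < rate / 2`.
#' @param order filter order per pass (default 4).
#' @return A filtered `eeg_recording` (`units_state = "filtered"`), same
#'   shape and channel order.
#' @export
bandpass_filter <- function(rec, low = 2, high = 40, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf(
      "invalid band edges: need 0 < low < high < rate/2 (got %g, %g, Nyquist %g)",
      low, high, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  recording(out, rate = rec$rate, channel_ids = rec$channel_ids,
            units_state = "filtered")
}

#' Per-channel standardization and min-max normalization
#'
#' Each channel is z-scored (subtract mean, divide by standard deviation)
#' and then min-max rescaled so its amplitude lies in \[0, 1\], the range
#' the completion network expects. All four statistics are returned so the
#' transform can be inverted exactly, and so that statistics estimated on a
#' training session can be applied unchanged to a test session (avoiding
#' test-set leakage).
#'
#' @param rec an `eeg_recording` (typically `"filtered"`).
#' @return A list with `rec`, the normalized recording, and `params`, a
#'   `normalization_params` object (per-channel `mean`, `sd`, `min`, `max`,
#'   where min/max are taken after z-scoring).
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  mu <- rowMeans(rec$data)
  sdv <- apply(rec$data, 1, stats::sd)
  if (any(sdv <= .Machine$double.eps)) {
    stop("cannot normalize: channel(s) with zero variance: ",
         paste(rec$channel_ids[sdv <= .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  }
  z <- (rec$data - mu) / sdv
  lo <- apply(z, 1, min)
  hi <- apply(z, 1, max)
  if (any(hi - lo <= .Machine$double.eps)) {
    stop("cannot normalize: degenerate channel range", call. = FALSE)
  }
  out <- (z - lo) / (hi - lo)
  params <- structure(list(mean = mu, sd = sdv, min = lo, max = hi,
                           channel_ids = rec$channel_ids),
                      class = "normalization_params")
  list(rec = recording(out, rate = rec$rate, channel_ids = rec$channel_ids,
                       units_state = "normalized"),
       params = params)
}

#' Apply stored normalization parameters to another recording
#'
#' Used to carry training-session statistics onto a test session. Values may
#' fall slightly outside \[0, 1\] when the new session's range exceeds the
#' training range; the result is therefore tagged `"filtered"` unless it
#' fits the unit interval.
#'
#' @param rec an `eeg_recording` in the same units as the recording the
#'   params were estimated from.
#' @param params a `normalization_params` object.
#' @return The affinely mapped `eeg_recording`.
#' @export
apply_normalization <- function(rec, params) {
  .check_norm_match(rec, params)
  z <- (rec$data - params$mean) / params$sd
  out <- (z - params$min) / (params$max - params$min)
  state <- if (min(out) >= -1e-9 && max(out) <= 1 + 1e-9) "normalized"
           else "filtered"
  recording(out, rate = rec$rate,
            channel_ids = rec$channel_ids, units_state = state)
}

#' Invert the normalization transform
#'
#' @param rec a normalized `eeg_recording`.
#' @param params the `normalization_params` returned by
#'   [normalize_recording()].
#' @return The recording mapped back to filtered units.
#' @export
denormalize_recording <- function(rec, params) {
  .check_norm_match(rec, params)
  z <- rec$data * (params$max - params$min) + params$min
  out <- z * params$sd + params$mean
  recording(out, rate = rec$rate, channel_ids = rec$channel_ids,
            units_state = "filtered")
}

.check_norm_match <- function(rec, params) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(params, "normalization_params"))
  if (nrow(rec$data) != length(params$mean) ||
      !identical(rec$channel_ids, params$channel_ids)) {
    stop("normalization params do not match the recording's channels",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Invert normalization for a single channel's signal
#'
#' Maps one channel of model output (normalized units) back to filtered
#' units using that channel's stored statistics.
#'
#' @param x numeric vector in normalized units.
#' @param params a `normalization_params` object.
#' @param id the channel id whose statistics to use.
#' @return Numeric vector in filtered units.
#' @export
denormalize_signal <- function(x, params, id) {
  i <- match(as.integer(id), params$channel_ids)
  if (is.na(i)) stop("unknown channel id: ", id, call. = FALSE)
  (x * (params$max[i] - params$min[i]) + params$min[i]) * params$sd[i] +
    params$mean[i]
}
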