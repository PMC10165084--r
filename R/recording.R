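#' Multichannel EEG recording container
#'
#' A recording holds a channels-by-samples potential matrix together with
#' its sampling rate, channel ids (matching an electrode layout) and a
#' `units_state` tag tracking where the data sit in the preprocessing chain:
#' `"raw"` (as acquired), `"filtered"` (band-passed) or `"normalized"`
#' (per-channel standardized and min-max rescaled to \[0, 1\]).
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling frequency in Hz (> 0).
#' @param channel_ids integer channel ids, one per row of `data`.
#' @param units_state one of `"raw"`, `"filtered"`, `"normalized"`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, rate, channel_ids = seq_len(nrow(data)),
                      units_state = "raw") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("recording data must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("'rate' must be a single positive number", call. = FALSE)
  }
  channel_ids <- as.integer(channel_ids)
  if (length(channel_ids) != nrow(data) || anyDuplicated(channel_ids)) {
    stop("'channel_ids' must match the rows of 'data' and be unique",
         call. = FALSE)
  }
  units_state <- match.arg(units_state, c("raw", "filtered", "normalized"))
  if (units_state == "normalized" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9)) {
    stop("normalized recordings must lie in [0, 1]", call. = FALSE)
  }
  structure(list(data = data, rate = as.numeric(rate),
                 channel_ids = channel_ids, units_state = units_state),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), x$rate, x$units_state))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Extract one channel's signal as a numeric vector
#'
#' @param rec an `eeg_recording`.
#' @param id a channel id present in `rec$channel_ids`.
#' @return Numeric vector of samples.
#' @export
channel_signal <- function(rec, id) {
  i <- match(as.integer(id), rec$channel_ids)
  if (is.na(i)) stop("unknown channel id: ", id, call. = FALSE)
  rec$data[i, ]
}

#' Read a multichannel recording from disk
#'
#' Two formats are supported. `"delimited"` is a plain-text table: a header
#' row of channel ids, then one row per sample, one column per channel
#' (tab-separated). `"edf"` is the European Data Format (16-bit); see
#' [write_recording()] for the writer. The format is inferred from the file
#' extension when not given.
#'
#' @param path file path.
#' @param format `"delimited"`, `"edf"`, or `NULL` to infer from extension.
#' @param rate sampling rate in Hz, required for delimited files (which do
#'   not carry one); default 250.
#' @return An `eeg_recording` in `"raw"` units state, channel order as
#'   stored in the file.
#' @export
read_recording <- function(path, format = NULL, rate = 250) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  }
  format <- match.arg(format, c("delimited", "edf"))
  if (format == "edf") return(read_edf(path))
  tab <- utils::read.delim(path, check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    stop("empty or malformed delimited recording: ", path, call. = FALSE)
  }
  m <- t(as.matrix(tab))
  if (!is.numeric(m) || anyNA(m)) {
    stop("malformed delimited recording (non-numeric or missing cells): ",
         path, call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(colnames(tab)))
  if (anyNA(ids)) ids <- seq_len(nrow(m))
  recording(m, rate = rate, channel_ids = ids, units_state = "raw")
}

#' Write a multichannel recording to disk
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @param format `"delimited"` or `"edf"`; inferred from the extension when
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  }
  format <- match.arg(format, c("delimited", "edf"))
  if (format == "edf") return(write_edf(rec, path))
  tab <- as.data.frame(t(rec$data))
  names(tab) <- rec$channel_ids
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
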