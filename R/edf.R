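# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores 16-bit integers with a per-signal affine map between digital
# and physical ranges, so a write/read round trip quantizes amplitudes to
# (phys_max - phys_min) / 65534. The writer emits a single data record
# spanning the whole recording, which is sufficient for the fixed-length
# recordings this package manipulates.

.edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = " ")
}

.edf_num <- function(x, n) {
  s <- formatC(x, format = "g", digits = n - 2)
  if (nchar(s) > n) s <- substr(s, 1, n)
  .edf_pad(s, n)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) {
    stop("truncated EDF header: ", path, call. = FALSE)
  }
  field <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  n_rec <- as.integer(field(237, 8))
  rec_dur <- as.numeric(field(245, 8))
  ns <- as.integer(field(253, 4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L) {
    stop("malformed EDF header: ", path, call. = FALSE)
  }
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256 * ns) {
    stop("truncated EDF signal header: ", path, call. = FALSE)
  }
  sfield <- function(block_from, len, i) {
    from <- block_from * ns + (i - 1) * len + 1
    trimws(substr(sig_hdr, from, from + len - 1))
  }
  labels <- vapply(1:ns, function(i) sfield(0, 16, i), "")
  pmin <- as.numeric(vapply(1:ns, function(i) sfield(16 + 80 + 8, 8, i), ""))
  pmax <- as.numeric(vapply(1:ns, function(i) sfield(16 + 80 + 16, 8, i), ""))
  dmin <- as.numeric(vapply(1:ns, function(i) sfield(16 + 80 + 24, 8, i), ""))
  dmax <- as.numeric(vapply(1:ns, function(i) sfield(16 + 80 + 32, 8, i), ""))
  nspr <- as.integer(vapply(1:ns, function(i) sfield(216, 8, i), ""))
  if (anyNA(c(pmin, pmax, dmin, dmax, nspr))) {
    stop("malformed EDF signal header: ", path, call. = FALSE)
  }
  dat <- matrix(0, nrow = ns, ncol = 0)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec <- matrix(NA_real_, nrow = ns, ncol = max(nspr))
    for (i in 1:ns) {
      v <- readBin(con, "integer", n = nspr[i], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < nspr[i]) stop("truncated EDF data: ", path,
                                    call. = FALSE)
      rec[i, seq_len(nspr[i])] <- v
    }
    chunks[[r]] <- rec
  }
  dig <- do.call(cbind, chunks)
  phys <- (dig - dmin) * (pmax - pmin) / (dmax - dmin) + pmin
  rate <- nspr[1] / rec_dur
  ids <- suppressWarnings(as.integer(sub("^Ch\\s*", "", labels)))
  if (anyNA(ids) || anyDuplicated(ids)) ids <- seq_len(ns)
  recording(phys, rate = rate, channel_ids = ids, units_state = "raw")
}

write_edf <- function(rec, path) {
  d <- rec$data
  ns <- nrow(d)
  n <- ncol(d)
  pmin <- apply(d, 1, min)
  pmax <- apply(d, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32767
  dmax <- 32767
  dig <- round((d - pmin) * (dmax - dmin) / (pmax - pmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(.edf_pad("0", 8))
  put(.edf_pad("X X X X", 80))
  put(.edf_pad("Startdate X X X X", 80))
  put(.edf_pad("01.01.00", 8))
  put(.edf_pad("00.00.00", 8))
  put(.edf_pad(256 * (1 + ns), 8))
  put(.edf_pad("", 44))
  put(.edf_pad(1, 8))
  put(.edf_num(n / rec$rate, 8))
  put(.edf_pad(ns, 4))
  for (i in 1:ns) put(.edf_pad(paste0("Ch ", rec$channel_ids[i]), 16))
  for (i in 1:ns) put(.edf_pad("", 80))
  for (i in 1:ns) put(.edf_pad("uV", 8))
  for (i in 1:ns) put(.edf_num(pmin[i], 8))
  for (i in 1:ns) put(.edf_num(pmax[i], 8))
  for (i in 1:ns) put(.edf_pad(dmin, 8))
  for (i in 1:ns) put(.edf_pad(dmax, 8))
  for (i in 1:ns) put(.edf_pad("", 80))
  for (i in 1:ns) put(.edf_pad(n, 8))
  for (i in 1:ns) put(.edf_pad("", 32))
  for (i in 1:ns) {
    writeBin(as.integer(dig[i, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}
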