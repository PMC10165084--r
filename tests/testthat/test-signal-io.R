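test_that("delimited recordings round-trip through disk", {
  rec <- toy_recording(n_ch = 22, n = 1000)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, tmp)
  back <- read_recording(tmp, rate = rec$rate)
  expect_equal(dim(back), c(22L, 1000L))
  expect_equal(back$data, rec$data, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$channel_ids, rec$channel_ids)
})

test_that("EDF recordings round-trip within 16-bit quantization", {
  rec <- toy_recording(n_ch = 6, n = 750)
  tmp <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, tmp)
  back <- read_recording(tmp)
  expect_equal(back$rate, 250)
  expect_equal(back$channel_ids, rec$channel_ids)
  quant <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65534
  expect_lt(max(abs(back$data - rec$data)), 2 * max(quant) + 1e-6)
})

test_that("malformed files are rejected", {
  tmp <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(1:100), tmp)
  expect_error(read_recording(tmp), "truncated|malformed")
  expect_error(read_recording("no/such/file.tsv"), "not found")
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2", "0.5\tnot_a_number"), tmp2)
  expect_error(read_recording(tmp2), "malformed")
})

test_that("band-pass filter attenuates out-of-band and preserves in-band sines", {
  rate <- 250
  tt <- seq_len(2000) / rate
  rec <- recording(rbind(sin(2 * pi * 50 * tt), sin(2 * pi * 10 * tt)),
                   rate = rate)
  out <- bandpass_filter(rec, 2, 40)
  expect_equal(out$units_state, "filtered")
  amp_at <- function(x, f) {
    sp <- Mod(stats::fft(x))[seq_len(length(x) / 2)]
    sp[round(f * length(x) / rate) + 1]
  }
  mid <- 500:1500  # avoid filtfilt edge transients
  atten_db <- 20 * log10(amp_at(out$data[1, mid], 50) /
                           amp_at(rec$data[1, mid], 50))
  expect_lt(atten_db, -20)
  ratio10 <- amp_at(out$data[2, mid], 10) / amp_at(rec$data[2, mid], 10)
  expect_lt(abs(ratio10 - 1), 0.05)
})

test_that("band edges are validated against the Nyquist frequency", {
  rec <- toy_recording()
  expect_error(bandpass_filter(rec, 30, 20), "invalid band")
  expect_error(bandpass_filter(rec, 2, 130), "invalid band")
  expect_error(bandpass_filter(rec, 0, 40), "invalid band")
})

test_that("band-pass filtering is linear", {
  rec1 <- toy_recording(seed = 1)
  rec2 <- toy_recording(seed = 2)
  mix <- recording(3 * rec1$data - 0.5 * rec2$data, rate = rec1$rate)
  f_mix <- bandpass_filter(mix)$data
  f_sep <- 3 * bandpass_filter(rec1)$data - 0.5 * bandpass_filter(rec2)$data
  expect_equal(f_mix, f_sep, tolerance = 1e-8)
})

test_that("normalization maps every channel onto [0, 1] and inverts exactly", {
  rec <- bandpass_filter(toy_recording(n_ch = 5))
  nz <- normalize_recording(rec)
  expect_equal(nz$rec$units_state, "normalized")
  expect_equal(apply(nz$rec$data, 1, min), rep(0, 5))
  expect_equal(apply(nz$rec$data, 1, max), rep(1, 5))

  back <- denormalize_recording(nz$rec, nz$params)
  expect_equal(back$data, rec$data, tolerance = 1e-9)

  # denormalize . normalize on a single channel too
  x <- nz$rec$data[3, ]
  expect_equal(denormalize_signal(x, nz$params, rec$channel_ids[3]),
               rec$data[3, ], tolerance = 1e-9)
})

test_that("normalization rejects constant channels and mismatched params", {
  rec <- recording(rbind(rep(5, 100), sin(seq_len(100))), rate = 250)
  expect_error(normalize_recording(rec), "zero variance")

  nz <- normalize_recording(toy_recording(n_ch = 4))
  rec3 <- toy_recording(n_ch = 3)
  expect_error(denormalize_recording(rec3, nz$params), "do not match")
})

test_that("an all-0.5 normalized channel denormalizes to the stored mid-range", {
  nz <- normalize_recording(bandpass_filter(toy_recording(n_ch = 2)))
  flat <- nz$rec
  flat$data[1, ] <- 0.5
  back <- denormalize_recording(flat, nz$params)
  mid <- (0.5 * (nz$params$max[1] - nz$params$min[1]) + nz$params$min[1]) *
    nz$params$sd[1] + nz$params$mean[1]
  expect_equal(unique(round(back$data[1, ], 12)), round(mid, 12))
})

test_that("stored training statistics transfer to a second session", {
  tr <- bandpass_filter(toy_recording(seed = 1))
  te <- bandpass_filter(toy_recording(seed = 2))
  nz <- normalize_recording(tr)
  mapped <- apply_normalization(te, nz$params)
  # same affine map as normalizing manually with train statistics
  z <- (te$data - nz$params$mean) / nz$params$sd
  expect_equal(mapped$data, (z - nz$params$min) /
                 (nz$params$max - nz$params$min), ignore_attr = TRUE)
})
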