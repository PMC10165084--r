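test_that("mse matches its definitional loop and handles edge cases", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  set.seed(21)
  P <- rnorm(101); Ph <- rnorm(101)
  acc <- 0
  for (l in seq_along(P)) acc <- acc + (P[l] - Ph[l])^2
  expect_equal(mse(P, Ph), acc / length(P), tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), "equal length")
  expect_error(mse(numeric(0), numeric(0)), "empty")
})

test_that("pearson rho matches the definitional formula and its invariances", {
  set.seed(22)
  P <- rnorm(200); Ph <- 0.6 * P + rnorm(200)
  num <- sum((P - mean(P)) * (Ph - mean(Ph)))
  den <- sqrt(sum((P - mean(P))^2) * sum((Ph - mean(Ph))^2))
  expect_equal(pearson_rho(P, Ph), num / den, tolerance = 1e-12)

  expect_equal(pearson_rho(P, 3 * P + 0.2), 1)
  expect_equal(pearson_rho(P, -P), -1)
  # invariance under positive affine transforms of either argument
  expect_equal(pearson_rho(2.3 * P - 1, 0.4 * Ph + 7), pearson_rho(P, Ph))
  expect_error(pearson_rho(P, rep(1, 200)), "constant")
})

test_that("baseline correction zeroes the mean, is idempotent, preserves rho", {
  expect_equal(baseline_correct(rep(0.7, 50)), rep(0, 50))
  set.seed(23)
  x <- rnorm(300, mean = 2)
  bc <- baseline_correct(x)
  expect_lt(abs(mean(bc)), 1e-12)
  expect_equal(baseline_correct(bc), bc)
  y <- rnorm(300)
  expect_equal(pearson_rho(bc, y), pearson_rho(x, y))
})

test_that("amplitude correction equalizes total absolute amplitude", {
  set.seed(24)
  P <- rnorm(100)
  ac <- amplitude_correct(P, 2 * P)
  expect_equal(ac$alpha, 0.5)
  expect_equal(ac$corrected, P)
  expect_equal(amplitude_correct(P, P)$alpha, 1)
  Ph <- rnorm(100)
  ac2 <- amplitude_correct(P, Ph)
  expect_equal(sum(abs(ac2$corrected)), sum(abs(P)), tolerance = 1e-12)
  expect_equal(pearson_rho(P, ac2$corrected), pearson_rho(P, Ph))
  expect_error(amplitude_correct(P, rep(0, 100)), "all-zero")
})

test_that("interpolation weights follow the inverse-distance law", {
  lay <- build_2a_layout()
  rec <- toy_recording(n_ch = 22, n = 400)
  # equidistant ring around Cz: equal quarters
  res <- interpolate_channel(rec, lay, c(1, 8, 12, 20), 10)
  expect_equal(res$weights$eta, rep(0.25, 4))
  expect_equal(res$signal,
               as.numeric(colMeans(rec$data[c(1, 8, 12, 20), ])))

  # hand-built distances (1,1,1,2) -> eta = (2/7, 2/7, 2/7, 1/7)
  lay2 <- electrode_layout(1:5, paste0("E", 1:5),
                           x_cm = c(1, 0, -1, 0, 0),
                           y_cm = c(0, 1, 0, -2, 0))
  rec5 <- toy_recording(n_ch = 5, n = 100)
  res2 <- interpolate_channel(rec5, lay2, 1:4, 5)
  expect_equal(res2$weights$eta, c(2, 2, 2, 1) / 7)

  expect_equal(sum(res2$weights$eta), 1)
  expect_error(interpolate_channel(rec5, lay2, c(1, 2, 5), 5), "must not")
})

test_that("interpolation weights are permutation-equivariant in the inputs", {
  lay <- build_2a_layout()
  rec <- toy_recording(n_ch = 22, n = 200)
  a <- interpolate_channel(rec, lay, c(2, 6, 14, 18), 10)
  b <- interpolate_channel(rec, lay, c(18, 2, 14, 6), 10)
  expect_equal(a$signal, b$signal)
  expect_equal(a$weights[order(a$weights$channel), ],
               b$weights[order(b$weights$channel), ], ignore_attr = TRUE)
})

test_that("bad-channel flagging separates noise from faithful channels", {
  set.seed(25)
  comp <- as.numeric(scale(cumsum(rnorm(2000))))  # structured reference
  faithful <- comp + 0.05 * rnorm(2000)
  noise <- rnorm(2000)                            # independent channel
  expect_false(flag_bad_channel(faithful, comp)$flagged)
  res <- flag_bad_channel(noise, comp, rho_threshold = 0.5)
  expect_true(res$flagged)
  expect_lt(abs(res$rho), 0.2)
  expect_error(flag_bad_channel(noise, comp, rho_threshold = 1.2),
               "must lie in")

  # historical-MSE rule
  res2 <- flag_bad_channel(faithful, comp, reference_mse = 1e-6,
                           mse_factor = 2)
  expect_true(res2$flagged)
})

test_that("evaluate_completion composes corrections correctly", {
  set.seed(26)
  truth <- rnorm(500)
  m0 <- evaluate_completion(truth, truth, baseline = FALSE)
  expect_equal(m0$mse, 0)
  expect_equal(m0$rho, 1)
  expect_equal(m0$alpha, 1)

  # constant offset removed by baseline correction
  m1 <- evaluate_completion(truth, truth + 0.3, baseline = TRUE)
  expect_equal(m1$mse, 0, tolerance = 1e-12)
  expect_equal(m1$rho, 1)
  expect_gt(m1$mse_raw, 0.089)

  # exact rescale removed by amplitude correction
  m2 <- evaluate_completion(truth, 0.5 * truth, baseline = TRUE,
                            amplitude = TRUE)
  expect_equal(m2$mse, 0, tolerance = 1e-12)
  expect_equal(m2$alpha, 2, tolerance = 1e-12)
})
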