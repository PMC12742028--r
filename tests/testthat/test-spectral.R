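make_ts <- function(values, fs = 300, state = "rest") {
  parcel_ts(values, fs, rep(state, ncol(values)))
}

test_that("epoching follows the floor rule within state segments", {
  p <- session_protocol(c("rest", "SBminus"), c(7, 4), 300)
  ts <- generate_session(p, effect_spec(region_count = 1), seed = 1)
  expect_length(epoch_series(ts, 1), 11)
  expect_length(epoch_series(ts, 4), 1 + 1)   # floor(7/4) + floor(4/4)
  # 3.5 s segment -> 3 one-second epochs
  ts2 <- make_ts(matrix(rnorm(1050), 1), fs = 300)
  expect_length(epoch_series(ts2, 1), 3)
  idx <- vapply(epoch_series(ts, 1), `[[`, 0L, "epoch_idx")
  expect_true(all(diff(idx) > 0))
})

test_that("psd_hanning identifies a 27 Hz tone and is Parseval-consistent", {
  fs <- 300
  t <- seq_len(fs) / fs
  tone <- matrix(sin(2 * pi * 27 * t), 1)
  psd <- psd_hanning(tone, fs)
  expect_equal(psd$frequencies[which.max(psd$power[1, ])], 27)
  expect_error(psd_hanning(matrix(rnorm(2 * fs), 1), fs), "re-epoch")
  # white-noise Parseval within 1% (all one-sided bins, 200 epochs)
  set.seed(4)
  tot <- replicate(200, {
    x <- matrix(rnorm(fs), 1)
    sum(psd_hanning(x, fs, fmax = 149)$power) / var(as.numeric(x))
  })
  expect_lt(abs(mean(tot) - 1), 0.01)
})

test_that("averaged white-noise spectrum is flat within 20% at every bin", {
  # 400 epoch averages put the per-bin sampling noise at ~5%, so a 20%
  # deviation would be a 4-sigma departure from flatness
  fs <- 300
  set.seed(7)
  P <- Reduce(`+`, lapply(1:400, function(i)
    psd_hanning(matrix(rnorm(fs), 1), fs)$power)) / 400
  expect_true(all(abs(P / mean(P) - 1) < 0.2))
})

test_that("power of independent signals adds in quadrature on average", {
  fs <- 300
  set.seed(8)
  diffs <- replicate(50, {
    a <- rnorm(fs); b <- rnorm(fs)
    pa <- psd_hanning(matrix(a, 1), fs)$power
    pb <- psd_hanning(matrix(b, 1), fs)$power
    pab <- psd_hanning(matrix(a + b, 1), fs)$power
    mean(pab - pmax(pa, pb))
  })
  expect_gt(mean(diffs), 0)
})

test_that("aperiodic fit matches closed forms and rejects peaks", {
  f <- 1:90
  fit <- fit_aperiodic(matrix(10 * f^(-2), 1), frequencies = f)
  expect_equal(fit$exponent, 2, tolerance = 1e-10)
  expect_equal(fit$offset, 1, tolerance = 1e-10)
  flat <- fit_aperiodic(matrix(rep(5, 90), 1), frequencies = f)
  expect_equal(flat$exponent, 0, tolerance = 1e-10)
  # chi = 1.5 power law plus an alpha peak: recovered within 0.1
  peaked <- f^(-1.5) + 0.8 * exp(-(f - 10)^2 / 4)
  fitp <- fit_aperiodic(matrix(peaked, 1), frequencies = f)
  expect_lt(abs(fitp$exponent - 1.5), 0.1)
  expect_error(fit_aperiodic(matrix(1:4, 1), frequencies = 1:4,
                             fit_range = c(1, 4)), "fewer than 5")
})

test_that("aperiodic fit is scale-equivariant", {
  f <- 1:90
  set.seed(1)
  P <- matrix(f^(-1.3) * exp(rnorm(90, 0, 0.1)), 1)
  f1 <- fit_aperiodic(P, frequencies = f)
  f10 <- fit_aperiodic(10 * P, frequencies = f)
  expect_equal(f10$exponent, f1$exponent, tolerance = 1e-12)
  expect_equal(f10$offset, f1$offset + 1, tolerance = 1e-12)
})

test_that("corrected band power self-subtracts, sees peaks, and is gain-invariant", {
  fs <- 300
  # pure 1/f input (ideal power law, 50-epoch averaged chi-square noise):
  # the periodic residual vanishes in every band
  set.seed(3)
  f <- 1:90
  P <- matrix(colMeans(matrix(rexp(50 * 90), 50)) * f^(-1.5), 1)
  psd0 <- structure(list(frequencies = f, power = P),
                    class = "psd_estimate")
  fit0 <- fit_aperiodic(psd0)
  for (b in default_bands())
    expect_lt(abs(corrected_band_power(psd0, fit0, b)), 0.05)

  t <- seq_len(fs) / fs
  set.seed(9)
  base <- rnorm(fs, sd = 2)
  epoch <- matrix(base + 3 * sin(2 * pi * 27 * t), 1)
  psd <- psd_hanning(epoch, fs)
  fit <- fit_aperiodic(psd)
  b27 <- corrected_band_power(psd, fit, default_bands()$beta27)
  hi <- corrected_band_power(psd, fit, default_bands()$gamma_high)
  expect_gt(b27, hi)
  # doubling the oscillation strictly increases the corrected value
  epoch2 <- matrix(base + 6 * sin(2 * pi * 27 * t), 1)
  psd2 <- psd_hanning(epoch2, fs)
  b27_2 <- corrected_band_power(psd2, fit_aperiodic(psd2),
                                default_bands()$beta27)
  expect_gt(b27_2, b27)
  # gain invariance is exact
  psd_g <- psd
  psd_g$power <- psd$power * 7.3
  expect_equal(corrected_band_power(psd_g, fit_aperiodic(psd_g),
                                    default_bands()$beta27),
               b27, tolerance = 1e-12)
  expect_error(corrected_band_power(psd, fit,
                                    band_definition("x", 33.2, 33.8)),
               "empty band")
})

test_that("spectral feature table has the documented shape", {
  p <- default_protocol()
  ts <- generate_session(p, effect_spec(region_count = 3), seed = 2)
  tab <- spectral_feature_table(ts, bands = default_bands()["beta27"])
  expect_equal(nrow(tab), 900)
  expect_equal(unname(table(tab$state)["rest"]), 300, ignore_attr = TRUE)
  expect_equal(sum(startsWith(names(tab), "beta27__")), 3)
  expect_equal(sum(startsWith(names(tab), "aperiodic__")), 3)
  # exponent-only table under an empty band list
  short <- session_protocol("rest", 5, 300)
  ts2 <- generate_session(short, effect_spec(region_count = 2), seed = 2)
  tab2 <- spectral_feature_table(ts2, bands = list())
  expect_equal(feature_columns(tab2),
               paste0("aperiodic__", c("region_001", "region_002")))
})

test_that("planted generator exponent is recovered within 0.1 from 60 s", {
  p <- session_protocol("rest", 60, 300)
  eff <- effect_spec(region_count = 2, complexity = 0, exponent = 1.5)
  ts <- generate_session(p, eff, seed = 21)
  P <- Reduce(`+`, lapply(epoch_series(ts, 1), function(e)
    psd_hanning(e$values, 300)$power)) / 60
  fit <- fit_aperiodic(P, frequencies = 1:90)
  expect_true(all(abs(fit$exponent - 1.5) < 0.1))
})
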