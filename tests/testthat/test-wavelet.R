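# Independent oracle: raw FFT periodogram argmax period.
periodogram_period <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  k <- 2:floor(n / 2)
  n / (k[which.max(p[k])] - 1)
}

test_that("a pure sinusoid's dominant period matches the periodogram", {
  t <- 1:256
  x <- sin(2 * pi * t / 8)
  expect_equal(periodogram_period(x), 8)
  ws <- cwt_morlet(x)
  dp <- dominant_period(ws)
  expect_gt(dp$period, 7.5)
  expect_lt(dp$period, 8.5)
  expect_false(dp$boundary)
})

test_that("wavelet and periodogram argmax agree across periods", {
  t <- 1:128
  step <- 2^(1 / 20)
  for (P in c(4, 6.5, 8, 12)) {
    x <- sin(2 * pi * t / P)
    wp <- dominant_period(cwt_morlet(x))$period
    pp <- periodogram_period(x)
    expect_lt(abs(log2(wp / pp)), log2(step) + log2(130 / 126))
  }
})

test_that("two mixed sinusoids give two average-power peaks", {
  t <- 1:256
  x <- sin(2 * pi * t / 4) + sin(2 * pi * t / 16)
  ws <- cwt_morlet(x)
  ap <- ws$avg_power
  locmax <- which(ap > c(-Inf, head(ap, -1)) & ap > c(tail(ap, -1), -Inf))
  pk <- ws$periods[locmax[order(ap[locmax], decreasing = TRUE)][1:2]]
  expect_true(any(abs(log2(pk / 4)) < 0.15))
  expect_true(any(abs(log2(pk / 16)) < 0.15))
})

test_that("white noise has no reproducible dominant period", {
  # restrict the ladder to the COI-interpretable band (period <~ n/3)
  per <- vapply(1:8, function(s) {
    set.seed(s)
    dominant_period(cwt_morlet(rnorm(64), J = 68))$period
  }, numeric(1))
  expect_gt(length(unique(per)), 3)
})

test_that("degenerate series are refused", {
  expect_error(cwt_morlet(rep(3, 32)), "constant")
  expect_error(cwt_morlet(rnorm(5)), "too short")
})

test_that("power and the dominant period are scale invariant", {
  set.seed(3)
  x <- sin(2 * pi * (1:64) / 6.5) + rnorm(64, 0, 0.3)
  w1 <- white_noise_test(cwt_morlet(x), n_sim = 60, seed = 1)
  w2 <- white_noise_test(cwt_morlet(x * 1000), n_sim = 60, seed = 1)
  expect_equal(w1$power, w2$power, tolerance = 1e-10)
  expect_equal(w1$pvalues, w2$pvalues)
  expect_equal(dominant_period(w1)$period, dominant_period(w2)$period)
})

test_that("a strong cycle is significant against white noise; seeded runs repeat", {
  t <- 1:64
  set.seed(4)
  x <- sin(2 * pi * t / 8) + rnorm(64, 0, sqrt(1 / 20))   # SNR ~ 10
  ws <- white_noise_test(cwt_morlet(x), n_sim = 200, seed = 5)
  dp <- dominant_period(ws)
  expect_lt(abs(log2(dp$period / 8)), log2(2^(1 / 20)) * 1.5)
  expect_lte(dp$p_value, 0.05)
  expect_true(all(dp$ci >= min(ws$periods) & dp$ci <= max(ws$periods)))
  ws2 <- white_noise_test(cwt_morlet(x), n_sim = 200, seed = 5)
  expect_identical(ws$pvalues, ws2$pvalues)
})

test_that("the white-noise test is calibrated near its nominal level", {
  set.seed(6)
  fp <- replicate(20, {
    ws <- white_noise_test(cwt_morlet(rnorm(64)), n_sim = 60)
    mean(ws$pvalues <= 0.05)
  })
  expect_lt(mean(fp), 0.12)
})

test_that("ridges are flat for a stationary cycle and rise for a chirp", {
  t <- 1:128
  ws <- cwt_morlet(sin(2 * pi * t / 10))
  r <- wavelet_ridge(ws, threshold = 0.9)
  inside <- r[ws$coi[match(r$time, ws$times)] > r$period, ]
  expect_gt(nrow(inside), 20)
  expect_lt(max(abs(log2(inside$period / 10))), 0.15)
  # chirp: instantaneous period drifts 6 -> 10
  p_inst <- 6 + 4 * t / 128
  phase <- 2 * pi * cumsum(1 / p_inst)
  wc <- cwt_morlet(sin(phase))
  rc <- wavelet_ridge(wc, threshold = 0.9)
  rc <- rc[wc$coi[match(rc$time, wc$times)] > rc$period, ]
  expect_gt(cor(rc$time, rc$period, method = "spearman"), 0.5)
})

test_that("boundary-only structure is flagged at the ladder edge", {
  x <- (1:32)^1.5                      # monotone trend, no cycle
  dp <- dominant_period(cwt_morlet(x))
  expect_true(dp$boundary)
})

test_that("period posterior over draws behaves at its degenerate limits", {
  t <- 1:32
  x <- sin(2 * pi * t / 6.5) + 0.1
  M <- matrix(rep(x, 30), nrow = 30, byrow = TRUE)
  pp <- period_posterior(M)
  expect_equal(pp$q025, pp$q975)
  expect_lt(abs(log2(pp$mean / 6.5)), 0.1)
  set.seed(7)
  Mn <- matrix(rnorm(30 * 32), nrow = 30)
  ppn <- period_posterior(Mn)
  expect_gt(ppn$q975 / ppn$q025, 1.5)   # wide posterior under noise
})

test_that("spectra export as long-format CSV", {
  ws <- white_noise_test(cwt_morlet(sin(2 * pi * (1:32) / 6)), n_sim = 50,
                         seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(ws, f)
  d <- read.csv(f)
  expect_equal(nrow(d), length(ws$periods) * length(ws$times))
  expect_true(all(c("time", "period", "power", "p_value") %in% names(d)))
})
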