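# Preprocessing chain: common average reference, high-gamma envelope,
# baseline z-scoring.

toy_raw <- function(samples, fs = 512) {
  n <- nrow(samples)
  raw_ecog(samples, fs, cbind(seq_len(n), rep(1L, n)))
}

test_that("common average reference subtracts the grand scalar mean", {
  x <- toy_raw(matrix(5, 3, 100))
  expect_true(all(common_average_reference(x)$samples == 0))
  set.seed(1)
  z <- matrix(rnorm(300), 3)
  z <- z - mean(z)
  expect_equal(common_average_reference(toy_raw(z))$samples, z)
  two <- toy_raw(rbind(rep(1, 50), rep(3, 50)))
  expect_equal(common_average_reference(two)$samples,
               rbind(rep(-1, 50), rep(1, 50)))
  # bad channels are excluded from the mean
  xb <- raw_ecog(rbind(rep(1, 50), rep(3, 50), rep(100, 50)), 512,
                 cbind(1:3, 1), bad_channels = 3L)
  expect_equal(common_average_reference(xb)$samples[1:2, ],
               rbind(rep(-1, 50), rep(1, 50)))
  allbad <- raw_ecog(matrix(1, 2, 50), 512, cbind(1:2, 1), bad_channels = 1:2)
  expect_error(common_average_reference(allbad), "valid")
})

test_that("high-gamma envelope passes 100 Hz, rejects 10 Hz, outputs 125 frames/s", {
  fs <- 512
  t <- seq_len(fs * 2) / fs
  A <- 3
  sig <- rbind(A * sin(2 * pi * 100 * t), A * sin(2 * pi * 10 * t))
  x <- raw_ecog(sig, fs, cbind(c(1, 2), c(1, 1)))
  env <- high_gamma_envelope(x)
  expect_equal(env$frame_rate, 125)
  expect_equal(dim(env$values)[1], floor(length(t) * 125 / fs))
  mid <- 50:200
  expect_lt(abs(mean(env$values[mid, 1, 1]) - A) / A, 0.15)
  expect_lt(mean(env$values[mid, 2, 1]), 0.05 * A)
  expect_error(high_gamma_envelope(toy_raw(matrix(0, 1, 100), fs = 350),
               band = c(70, 200)), "too low")
})

test_that("band-pass attenuation exceeds 20 dB at 35 and 300 Hz", {
  fs <- 2048
  t <- seq_len(fs) / fs
  gain_at <- function(f) {
    bf <- signal::butter(4, c(70, 150) / (fs / 2), type = "pass")
    out <- signal::filtfilt(bf, sin(2 * pi * f * t))
    max(abs(out[300:1700]))
  }
  expect_lt(20 * log10(gain_at(35)), -20)
  expect_lt(20 * log10(gain_at(300)), -20)
  expect_gt(20 * log10(gain_at(110)), -3)
})

test_that("baseline z-scoring centres, scales, and errors on degenerate baselines", {
  set.seed(4)
  d <- c(200L, 2L, 2L)
  mu <- c(1, 2, 3, 4); sg <- c(0.5, 1, 2, 4)
  vals <- array(rnorm(prod(d)), d)
  for (e in 1:4) vals[, (e - 1) %% 2 + 1, (e - 1) %/% 2 + 1] <-
      vals[, (e - 1) %% 2 + 1, (e - 1) %/% 2 + 1] * sg[e] + mu[e]
  env <- ecog_tensor(vals)
  base <- lapply(1:5, function(i) {
    b <- array(rnorm(prod(c(2000L, 2L, 2L))), c(2000L, 2L, 2L))
    for (e in 1:4) b[, (e - 1) %% 2 + 1, (e - 1) %/% 2 + 1] <-
        b[, (e - 1) %% 2 + 1, (e - 1) %/% 2 + 1] * sg[e] + mu[e]
    b
  })
  z <- zscore_to_baseline(env, base)
  zm <- ecog_matrix(z)
  expect_true(all(abs(colMeans(zm)) < 0.15))
  expect_true(all(abs(apply(zm, 2, sd) - 1) < 0.1))
  # constant-at-baseline-mean input maps to ~0
  cvals <- array(rep(mu, each = d[1]), c(d[1], 2, 2))
  flat <- ecog_matrix(zscore_to_baseline(ecog_tensor(cvals), base))
  expect_lt(max(abs(flat)), 0.1)
  # z-scoring with reference (0, 1) is the identity
  b01 <- list(array(rnorm(4e4), c(1e4, 2, 2)))
  env2 <- ecog_tensor(array(rnorm(prod(d)), d))
  z2 <- zscore_to_baseline(env2, b01)
  expect_equal(z2$values, env2$values, tolerance = 0.1)
  expect_error(zscore_to_baseline(env, array(1, c(50, 2, 2))), "variance")
})

test_that("the preprocessing chain is bitwise deterministic", {
  set.seed(9)
  sig <- matrix(rnorm(4 * 1024), 4)
  x <- raw_ecog(sig, 512, cbind(rep(1:2, 2), rep(1:2, each = 2)))
  r1 <- high_gamma_envelope(common_average_reference(x))
  r2 <- high_gamma_envelope(common_average_reference(x))
  expect_identical(r1$values, r2$values)
})
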