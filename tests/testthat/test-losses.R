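# Training objectives: MSS, one-third-octave bands, STOI+, supervision,
# reference, and the weighted totals.

test_that("MSS loss matches its closed form and is a symmetric premetric", {
  set.seed(5)
  S <- matrix(runif(40 * 256, 0.1, 1), 40)
  expect_equal(mss_loss(S, S), 0)
  fb <- t(mel_filterbank(80, 256))
  expected <- sum(S) + length(S) * log(2) +
    sum(S %*% fb) + length(S %*% fb) * log(2)
  expect_equal(mss_loss(2 * S, S), expected, tolerance = 1e-12)
  expect_equal(mss_loss(2 * S, S), mss_loss(S, 2 * S))
  expect_gt(mss_loss(S + 0.1, S), 0)
  expect_error(mss_loss(S, S[, 1:100]), "shape")
})

test_that("one-third octave analysis yields 15 bands up to ~4.3 kHz and conserves energy", {
  set.seed(6)
  x <- matrix(runif(40 * 256), 40)
  bd <- octave_band_norms(x)
  expect_identical(length(bd$centres), 15L)
  expect_equal(bd$centres[1], 150)
  expect_equal(max(bd$centres) * 2^(1 / 6), 4276, tolerance = 1)
  expect_true(all(bd$k2 > bd$k1))
  # energy within the covered bin range bounds the band energies
  expect_lte(sum(bd$norms^2), sum(x[, min(bd$k1):(max(bd$k2) - 1)]^2) + 1e-9)
  # a tone inside one band lands in exactly that band
  f <- spec_freqs(256)
  tone <- matrix(0, 35, 256)
  b8 <- which.min(abs(f - bd$centres[8]))
  tone[, b8] <- 1
  bn <- octave_band_norms(tone)$norms
  expect_true(all(bn[, 8] > 0) && all(bn[, -8] == 0))
  expect_error(octave_band_norms(x, f_max = 4000), "4.3")
})

test_that("STOI+ is 1 on self and positively scaled copies, near 0 on independent noise", {
  set.seed(9)
  x <- matrix(runif(63 * 256), 63)
  expect_equal(stoi_plus(x, x), 1, tolerance = 1e-9)
  expect_equal(stoi_plus(3.7 * x, x), 1, tolerance = 1e-9)
  m <- mean(replicate(40, stoi_plus(matrix(runif(40 * 256), 40),
                                    matrix(runif(40 * 256), 40))))
  expect_lt(abs(m), 0.03)
  expect_error(stoi_plus(x[1:20, ], x[1:20, ]), "30")
  # affine envelope invariance at segment level: PCC of band envelopes
  y <- x * 2 + matrix(0.05, 63, 256)   # near-affine in the band norms
  expect_gt(stoi_plus(y, x), 0.98)
})

test_that("supervision loss covers pitch and formants 1-4 only, with printed weights", {
  T <- 3L
  pm <- matrix(0, T, 18)
  rf <- matrix(0, T, 4)
  expect_equal(supervision_loss(pm, rep(0, T), rf), 0)
  pm[, 2] <- 10
  expect_equal(supervision_loss(pm, rep(0, T), rf), 0.1 * T * 100)
  pm2 <- pm; pm2[, 6] <- 99; pm2[, 7] <- 99     # formants 5, 6 unsupervised
  expect_equal(supervision_loss(pm2, rep(0, T), rf),
               supervision_loss(pm, rep(0, T), rf))
  pm3 <- pm; pm3[, 1] <- 2
  expect_equal(supervision_loss(pm3, rep(0, T), rf), 0.1 * T * 100 + T * 4)
  expect_error(supervision_loss(pm, rep(0, T + 1), rf), "frame")
})

test_that("reference loss weights all 18 parameters with the printed lambdas", {
  a <- matrix(0, 1, 18); b <- a
  expect_equal(reference_loss(a, b), 0)
  a[, 17] <- 1                                   # voice weight
  expect_equal(reference_loss(a, b), 1.8)
  a2 <- matrix(0, 1, 18); a2[, 14] <- 1          # broadband frequency
  expect_equal(reference_loss(a2, b), 10)
  set.seed(2)
  x <- matrix(rnorm(36), 2); y <- matrix(rnorm(36), 2)
  w <- loss_weights()$ref
  expect_equal(reference_loss(x, y, 2 * w), 2 * reference_loss(x, y, w))
})

test_that("weighted totals assemble their terms as printed", {
  set.seed(10)
  S <- matrix(runif(40 * 256, 0.05, 1), 40)
  p <- matrix(rnorm(40 * 18)^2, 40)
  f0 <- p[, 1]; fm <- p[, 2:5]
  w <- loss_weights()
  expect_equal(w$lambda1, 1.2)
  expect_equal(w$lambda2, 0.1)
  expect_equal(w$lambda3, 1)
  expect_equal(w$beta, c(0.1, 0.06, 0.03, 0.02))
  # perfect reconstruction and parameters: total = -lambda1 * STOI+ = -1.2
  expect_equal(autoencoder_total(S, S, p, f0, fm), -1.2, tolerance = 1e-9)
  # lambda1 = lambda2 = 0 reduces to the MSS loss
  w0 <- w; w0$lambda1 <- 0; w0$lambda2 <- 0
  S2 <- S * 1.3
  expect_equal(autoencoder_total(S2, S, p, f0, fm, w0), mss_loss(S2, S))
  # increasing supervision error with others fixed increases the total
  p_off <- p; p_off[, 2] <- p_off[, 2] + 50
  expect_gt(autoencoder_total(S2, S, p_off, f0, fm),
            autoencoder_total(S2, S, p, f0, fm))
  # decoder total: guidance = prediction reduces to the auto-encoder total
  expect_equal(decoder_total(S2, S, p, f0, fm, p),
               autoencoder_total(S2, S, p, f0, fm))
  w3 <- w; w3$lambda3 <- 0
  g <- p + 1
  expect_equal(decoder_total(S2, S, p, f0, fm, g, w3),
               autoencoder_total(S2, S, p, f0, fm))
  # 1-frame toy case: hand-summed terms
  S1 <- matrix(runif(30 * 256, 0.1, 1), 30)
  p1 <- matrix(abs(rnorm(30 * 18)), 30)
  g1 <- p1; g1[, 18] <- g1[, 18] + 2
  hand <- autoencoder_total(S1, S1, p1, p1[, 1], p1[, 2:5]) +
    1 * 1.5 * 30 * 4
  expect_equal(decoder_total(S1, S1, p1, p1[, 1], p1[, 2:5], g1), hand)
})

test_that("tape losses agree with their numeric forms and differentiate", {
  set.seed(11)
  x <- matrix(runif(40 * 256), 40)
  y <- matrix(runif(40 * 256), 40)
  fb <- t(mel_filterbank(80, 256))
  bi <- neurovox:::octave_band_matrix(256)
  tape <- neurovox:::nv_tape()
  xn <- neurovox:::tp_leaf(tape, x)
  ms <- neurovox:::tp_mss(tape, xn, y, fb)
  st <- neurovox:::tp_stoi(tape, xn, y, bi)
  expect_equal(ms$value, mss_loss(x, y), tolerance = 1e-9)
  expect_equal(st$value, stoi_plus(x, y), tolerance = 1e-6)
  L <- neurovox:::tp_add(tape, ms, st)
  neurovox:::tp_backward(tape, L)
  i <- 7; j <- 120; h <- 1e-6
  f <- function(xx) mss_loss(xx, y) + stoi_plus(xx, y)
  xp <- x; xp[i, j] <- xp[i, j] + h
  xm <- x; xm[i, j] <- xm[i, j] - h
  fd <- (f(xp) - f(xm)) / (2 * h)
  expect_lt(abs(xn$grad[i, j] - fd) / abs(fd), 1e-3)
})

test_that("STOI+ stays within [-1, 1] across seeded random spectrogram pairs", {
  set.seed(12)
  vals <- replicate(60, {
    a <- matrix(runif(31 * 256), 31)
    b <- a * runif(1, -1, 2) + matrix(rnorm(31 * 256, 0, 0.3), 31)^2
    stoi_plus(a, b)
  })
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
})
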