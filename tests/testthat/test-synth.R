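# Differentiable synthesizer: harmonic excitation, filter algebra, the
# soft voice/unvoice mix, and gradient fidelity.

test_that("harmonic excitation concentrates energy at pitch multiples", {
  H <- unclass(harmonic_excitation(rep(250, 40)))
  f <- spec_freqs(256)
  avg <- colMeans(H)
  # every harmonic bin (250 k Hz, k <= 32) is a local maximum
  for (k in c(1, 2, 3, 5, 10, 20, 32)) {
    b <- which.min(abs(f - 250 * k))
    expect_gte(avg[b], max(avg[c(b - 2, b + 2)], na.rm = TRUE) * 0.9)
  }
  # anti-aliasing: with f0 = 300 only 26 harmonics fit below 8 kHz, so
  # above 7900 Hz nothing but window-sidelobe leakage remains
  H300 <- colMeans(unclass(harmonic_excitation(rep(300, 40))))
  expect_gt(max(H300[f > 7700 & f <= 7862]), 0.5 * max(H300))
  expect_lt(max(H300[f > 7900]), 0.05 * max(H300))
})

test_that("zero pitch produces a silent excitation", {
  expect_lt(max(unclass(harmonic_excitation(rep(0, 20)))), 1e-6)
})

test_that("a rising pitch is tracked frame by frame", {
  f0 <- seq(150, 350, length.out = 50)
  H <- unclass(harmonic_excitation(f0))
  f <- spec_freqs(256)
  df <- 8000 / 256
  hits <- vapply(seq_along(f0), function(t) {
    b <- which.min(abs(f - f0[t]))
    # the bin nearest f0 is within one bin of a local spectral peak
    win <- H[t, max(1, b - 1):min(256, b + 1)]
    max(win) >= max(H[t, max(1, b - 3):min(256, b + 3)]) * 0.999
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("closed-form harmonic stack equals the direct 80-term sum", {
  set.seed(8)
  f0 <- runif(500, 0, 420)
  f0[sample(500, 40)] <- 0
  phi <- cumsum(f0 / 16000)
  n <- neurovox:::harmonic_count(f0, 80L, 8000)
  direct <- neurovox:::harmonic_bank_direct(phi, f0, 80L)
  closed <- neurovox:::harmonic_bank_eval(phi, n)
  expect_equal(closed$h, direct$h, tolerance = 1e-8)
  expect_equal(closed$dphi, direct$dphi, tolerance = 1e-6)
})

test_that("voiced component obeys linearity and band concentration", {
  s <- toy_speaker()
  p <- toy_params()
  # all formant amplitudes zero -> zero voiced component
  p0 <- p; p0$formant_a[] <- 0
  expect_equal(max(unclass(voice_component(p0, s))), 0)
  # homogeneity: doubling amplitudes doubles V
  p2 <- p; p2$formant_a <- 2 * p$formant_a
  expect_equal(unclass(voice_component(p2, s)), 2 * unclass(voice_component(p, s)),
               tolerance = 1e-10)
  # single active formant concentrates energy around f_1
  p1 <- p
  p1$formant_a[] <- 0; p1$formant_a[, 1] <- 1
  p1$formant_f[, 1] <- 800
  V <- unclass(voice_component(p1, s))
  f <- spec_freqs(256)
  bw <- bandwidth_from_center(800, s$bw_relation[1, ])
  inside <- sum(V[, abs(f - 800) <= 2 * bw]^2)
  expect_gt(inside / sum(V^2), 0.7)
})

test_that("unvoiced component is seeded-deterministic with energy tracking |F_u|^2", {
  s <- toy_speaker()
  p <- toy_params()
  expect_identical(unclass(unvoice_component(p, s, seed = 7)),
                   unclass(unvoice_component(p, s, seed = 7)))
  expect_false(identical(unclass(unvoice_component(p, s, seed = 7)),
                         unclass(unvoice_component(p, s, seed = 8))))
  p0 <- p; p0$formant_a[] <- 0; p0$a_bb[] <- 0
  expect_equal(max(unclass(unvoice_component(p0, s))), 0)
  # mean band energy over seeds is proportional to the squared filter
  T <- 30L
  pp <- toy_params(T)
  tape <- neurovox:::nv_tape()
  out <- neurovox:::synth_forward(tape, neurovox:::params_nodes(tape, pp),
                                  neurovox:::speaker_nodes_const(tape, s),
                                  T, 256L, matrix(0, T, 256))
  F2 <- out$Fu$value^2
  acc <- 0
  for (sd in 1:200) acc <- acc + unclass(unvoice_component(pp, s, seed = sd))^2
  acc <- acc / 200
  # correlation between E[U^2] and |F_u|^2 across cells (rows with signal)
  keep <- rowSums(F2) > 1e-8
  expect_gt(cor(as.vector(acc[keep, ]), as.vector(F2[keep, ])), 0.95)
})

test_that("the soft mix satisfies its algebraic identities and background floor", {
  s <- toy_speaker()
  p <- toy_params()
  T <- n_frames(p)
  B <- matrix(s$background, T, 256, byrow = TRUE)
  V <- unclass(voice_component(p, s))
  U <- unclass(unvoice_component(p, s, seed = 1))
  for (a in c(0, 0.5, 1)) {
    pa <- p; pa$alpha[] <- a
    S <- unclass(synthesize(pa, s, seed = 1))
    expect_equal(S, p$loudness * (a * V + (1 - a) * U) + B, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # loudness 0 -> background only
  pl <- p; pl$loudness[] <- 0
  expect_equal(unclass(synthesize(pl, s, seed = 1)), B, tolerance = 1e-12,
               ignore_attr = TRUE)
  # output never falls below the background spectrum
  S <- unclass(synthesize(p, s, seed = 2))
  expect_true(all(S >= B - 1e-12))
  # frame-count mismatch errors
  bad <- p; bad$alpha <- bad$alpha[-1]
  expect_error(synthesize(bad, s), "frame count")
})

test_that("synthesizer gradients match finite differences on a 5-frame toy input", {
  s <- toy_speaker()
  set.seed(21)
  T2 <- 5L
  p2 <- speech_params(
    f0 = c(210, 216, 222, 228, 234),
    formant_f = matrix(rep(c(480, 1400, 2600, 3600, 4600, 6100), each = T2), T2) +
      matrix(rnorm(T2 * 6, 0, 5), T2),
    formant_a = matrix(runif(T2 * 6, 0.2, 1), T2),
    f_bb = runif(T2, 3500, 4500), b_bb = runif(T2, 2500, 3500),
    a_bb = runif(T2, 0.2, 0.6), alpha = runif(T2, 0.2, 0.8),
    loudness = runif(T2, 0.5, 1.5))
  noise <- noise_excitation(T2, 256L, 5)
  tgt <- matrix(runif(T2 * 256), T2)
  loss_num <- function(p) {
    tape <- neurovox:::nv_tape()
    out <- neurovox:::synth_forward(tape, neurovox:::params_nodes(tape, p),
                                    neurovox:::speaker_nodes_const(tape, s),
                                    T2, 256L, noise)
    sum((out$S$value - tgt)^2)
  }
  tape <- neurovox:::nv_tape()
  pn <- neurovox:::params_nodes(tape, p2, leaf = TRUE)
  out <- neurovox:::synth_forward(tape, pn, neurovox:::speaker_nodes_const(tape, s),
                                  T2, 256L, noise)
  L <- neurovox:::tp_sum(tape, neurovox:::tp_square(tape,
                                                    neurovox:::tp_sub(tape, out$S, tgt)))
  neurovox:::tp_backward(tape, L)
  cases <- list(
    list("f0", "f0", 3, NULL, 1e-4), list("formant_f", "ff", 2, 1, 1e-3),
    list("formant_f", "ff", 4, 3, 1e-3), list("formant_a", "fa", 2, 2, 1e-5),
    list("f_bb", "f_bb", 3, NULL, 1e-3), list("b_bb", "b_bb", 3, NULL, 1e-3),
    list("a_bb", "a_bb", 2, NULL, 1e-5), list("alpha", "alpha", 4, NULL, 1e-5),
    list("loudness", "loudness", 1, NULL, 1e-5))
  for (cs in cases) {
    field <- cs[[1]]; node <- pn[[cs[[2]]]]; i <- cs[[3]]; j <- cs[[4]]; h <- cs[[5]]
    pp <- p2; pm <- p2
    if (is.null(j)) { pp[[field]][i] <- pp[[field]][i] + h
      pm[[field]][i] <- pm[[field]][i] - h
    } else { pp[[field]][i, j] <- pp[[field]][i, j] + h
      pm[[field]][i, j] <- pm[[field]][i, j] - h }
    fd <- (loss_num(pp) - loss_num(pm)) / (2 * h)
    an <- if (is.null(j)) node$grad[i] else node$grad[i, j]
    expect_lt(abs(an - fd) / max(abs(fd), 1e-6), 1e-3)
  }
})

test_that("Griffin-Lim inversion recovers tones and decreases its error", {
  f <- spec_freqs(256)
  S <- matrix(0, 40, 256)
  S[, which.min(abs(f - 1000))] <- 1
  gl <- spectrogram_to_waveform(nv_spectrogram(S), n_iter = 20, seed = 1)
  sp <- Mod(stats::fft(gl$wave * neurovox:::hann(length(gl$wave))))[1:2560]
  fr <- (0:2559) / length(gl$wave) * 16000
  expect_lt(abs(fr[which.max(sp)] - 1000), 20)
  expect_true(all(diff(gl$errors) <= 1e-8))
  # zero spectrogram -> silence
  gl0 <- spectrogram_to_waveform(nv_spectrogram(matrix(0, 10, 256)), n_iter = 3)
  expect_lt(max(abs(gl0$wave)), 1e-9)
})

test_that("WAV files round-trip", {
  w <- sin(2 * pi * 440 * (1:1600) / 16000) * 0.5
  path <- tempfile(fileext = ".wav")
  write_wav(w, path)
  rt <- read_wav(path)
  expect_equal(rt$fs, 16000)
  expect_equal(rt$wave, w, tolerance = 1e-3)
})
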