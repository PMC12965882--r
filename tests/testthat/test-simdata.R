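# Synthetic-data generator: invariants, determinism, and the recoverable
# electrode-to-parameter mapping.

test_that("generated trajectories satisfy every speech-parameter invariant", {
  for (s in 1:30) {
    p <- gen_word_params(seed = s)
    expect_silent(validate_speech_params(p))
    expect_true(all(p$alpha >= 0 & p$alpha <= 1))
    expect_true(all(p$b_bb > 2000))
  }
})

test_that("trajectories and pseudo-ECoG are seeded-deterministic", {
  p1 <- gen_word_params(seed = 4)
  p2 <- gen_word_params(seed = 4)
  expect_identical(as.matrix(p1), as.matrix(p2))
  expect_false(identical(as.matrix(p1), as.matrix(gen_word_params(seed = 5))))
  m <- gen_mapping(seed = 1)
  e1 <- gen_pseudo_ecog(p1, m, seed = 9)
  e2 <- gen_pseudo_ecog(p1, m, seed = 9)
  expect_identical(e1$values, e2$values)
})

test_that("voiced fraction tracks the configured target", {
  vf <- mean(vapply(1:60, function(s)
    mean(gen_word_params(synth_trial_spec(voiced_fraction = 0.7), seed = s)$alpha > 0.5),
    1))
  expect_lt(abs(vf - 0.7), 0.1)
  vf2 <- mean(vapply(1:40, function(s)
    mean(gen_word_params(synth_trial_spec(voiced_fraction = 0.4, n_segments = 4),
                         seed = s)$alpha > 0.5), 1))
  expect_lt(abs(vf2 - 0.4), 0.12)
})

test_that("generated speakers satisfy the learnable-parameter contract", {
  s <- gen_speaker("female", seed = 12)
  for (j in 1:7) expect_true(neurovox:::is_unimodal(s$proto[, j]))
  expect_identical(length(s$proto) + length(s$bw_relation) + length(s$background),
                   count_learnable_params("female"))
  expect_identical(s$raw$proto_raw, gen_speaker("female", seed = 12)$raw$proto_raw)
  sm <- gen_speaker("male", seed = 12)
  expect_identical(length(sm$background), 512L)
})

test_that("zero-weight electrodes carry pure noise", {
  m <- gen_mapping(seed = 1)
  silent <- which(rowSums(abs(m$weights)) == 0)[1:3]
  mx <- c()
  for (s in 1:30) {
    p <- gen_word_params(seed = s)
    e <- ecog_matrix(gen_pseudo_ecog(p, m, seed = 100 + s))
    pm <- as.matrix(p)
    for (el in silent) {
      cc <- suppressWarnings(abs(cor(e[, el], pm)))
      mx <- c(mx, mean(cc[is.finite(cc)]))
    }
  }
  expect_lt(mean(mx), 0.2)
})

test_that("a noiseless identity-like mapping reproduces the advanced parameter series", {
  p <- gen_word_params(seed = 3)
  W <- matrix(0, 4, 18); W[2, 1] <- 1
  m <- generative_mapping(W, lags = c(0, 2, 0, 0), noise_sd = 0, grid = c(2, 2))
  e <- ecog_matrix(gen_pseudo_ecog(p, m, seed = 1))
  ns <- neurovox:::param_norm_stats("female")
  z <- (p$f0 - ns$mu[1]) / ns$sd[1]
  T <- length(z)
  # the electrode leads the produced speech by its lag
  expect_equal(e[, 2], z[pmin(seq_len(T) + 2L, T)], tolerance = 1e-12)
  expect_true(all(e[, c(1, 3, 4)] == 0))
})

test_that("datasets are reproducible with a 7:1 split and background-floored spectrograms", {
  ds <- toy_dataset()
  expect_equal(length(ds$test), max(1, round(length(ds$trials) / 8)))
  ds2 <- make_dataset(24, mapping = gen_mapping(noise_sd = 0.1, seed = 43), seed = 42)
  expect_identical(ds$test, ds2$test)
  expect_identical(unclass(ds$trials[[5]]$spec), unclass(ds2$trials[[5]]$spec))
  expect_identical(ds$trials[[7]]$ecog$values, ds2$trials[[7]]$ecog$values)
  B <- min(ds$speaker$background)
  expect_true(all(unclass(ds$trials[[1]]$spec) >= B - 1e-12))
})

test_that("word-level splits hold out whole words", {
  ds <- make_dataset(24, seed = 3, split = "word")
  words_test <- unique(vapply(ds$trials[ds$test], function(t) t$word, 1))
  words_train <- unique(vapply(ds$trials[ds$train], function(t) t$word, 1))
  expect_length(intersect(words_test, words_train), 0)
})
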