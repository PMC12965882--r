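# Occlusion contribution analysis.

test_that("spectrogram PCC matches hand computations and flags degenerate input", {
  set.seed(3)
  S <- matrix(runif(20 * 256), 20)
  expect_equal(spectrogram_pcc(S, S), 1)
  expect_equal(spectrogram_pcc(-S + 2, S), -1)
  a <- matrix(c(1, 2, 3, 5), 2)
  b <- matrix(c(2, 1, 4, 6), 2)
  expect_equal(spectrogram_pcc(a, b), cor(as.vector(a), as.vector(b)))
  expect_error(spectrogram_pcc(matrix(1, 2, 2), b), "variance")
  expect_error(spectrogram_pcc(S, S[, 1:10]), "shape")
})

test_that("an electrode the decoder provably ignores contributes exactly zero", {
  ds <- toy_dataset()
  st <- decoder_state(toy_decoder_cfg("lstm", TRUE), seed = 4)
  # zero electrode (2, 1)'s weights in the LSTM input and every skip tap
  el <- 2L   # column-major position of grid (2, 1)
  E <- 64L
  st$params$l1d1_wx[el, ] <- 0
  st$params$skip_w[(0:7) * E + el, ] <- 0
  contrib <- electrode_contribution(st, ds$trials[ds$test], c(2L, 1L),
                                    speaker = ds$speaker)
  expect_identical(contrib, 0)
  # an already-zero (zero-variance) electrode likewise contributes zero
  ds0 <- ds
  for (i in ds0$test) ds0$trials[[i]]$ecog$values[, 5, 5] <- 0
  c0 <- electrode_contribution(decoder_state(toy_decoder_cfg("lstm", TRUE), seed = 4),
                               ds0$trials[ds0$test], c(5L, 5L), speaker = ds$speaker)
  expect_identical(c0, 0)
  expect_error(electrode_contribution(st, list(), c(1L, 1L)), "empty")
  expect_error(electrode_contribution(st, ds$trials[ds$test], c(9L, 9L),
                                      speaker = ds$speaker), "grid")
})

test_that("contribution maps have grid shape and reproducible entries", {
  ds <- toy_dataset()
  st <- decoder_state(toy_decoder_cfg("lstm", TRUE), seed = 4)
  test2 <- ds$trials[ds$test][1]
  cm <- contribution_map(st, test2, speaker = ds$speaker, seed = 1)
  expect_identical(dim(cm$contrib), dim(ds$trials[[1]]$ecog$valid_mask))
  cm2 <- contribution_map(st, test2, speaker = ds$speaker, seed = 1)
  expect_identical(cm$contrib, cm2$contrib)
  expect_true(all(is.finite(cm$contrib)))
})

test_that("the shuffled pairing is a seeded derangement", {
  for (s in 1:5) {
    p <- neurovox:::derangement(7L, seed = s)
    expect_false(any(p == 1:7))
    expect_setequal(p, 1:7)
  }
  expect_identical(neurovox:::derangement(9L, seed = 2),
                   neurovox:::derangement(9L, seed = 2))
})

test_that("noise-floor zeroing suppresses sub-floor contributions", {
  cm <- structure(list(contrib = matrix(c(0.2, 0.01, -0.01, 0.3), 2),
                       n_trials = 4L, noise_floor = NULL),
                  class = "contribution_map")
  fl <- structure(list(contrib = matrix(0.05, 2, 2), n_trials = 4L,
                       noise_floor = NULL), class = "contribution_map")
  out <- apply_noise_floor(cm, fl)
  expect_equal(out$contrib, matrix(c(0.2, 0, 0, 0.3), 2))
})
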