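# Speech encoder and auto-encoder training mechanics.

test_that("unit-interval outputs de-normalize onto their frequency ranges", {
  expect_equal(denormalize_frequency(0, c(80, 300)), 80)
  expect_equal(denormalize_frequency(1, c(80, 300)), 300)
  expect_equal(denormalize_frequency(0.5, c(80, 300)), 190)
  expect_error(denormalize_frequency(1.2, c(80, 300)))
  fr <- nv_freq_ranges("female")
  expect_true(all(fr[, 1] < fr[, 2]))
  expect_true(all(fr >= 0 & fr <= 8000 + 1e-6))
})

test_that("an untrained encoder still honors shape and range contracts", {
  cfg <- encoder_config(C = 16L, C_mel = 8L, n_conv = 2L, Dh = 12L)
  st <- list(params = with_seed(2, neurovox:::encoder_init(cfg)), config = cfg,
             trained = FALSE)
  spec <- toy_dataset()$trials[[2]]$spec
  p <- encode(spec, st)
  expect_identical(n_frames(p), nrow(spec))
  expect_false(attr(p, "trained"))
  expect_silent(validate_speech_params(p))
  # random spectrograms: outputs always within declared ranges
  set.seed(6)
  for (i in 1:5) {
    sp <- nv_spectrogram(matrix(runif(35 * 256, 0, 3), 35))
    pi <- encode(sp, st)
    expect_true(all(pi$f0 >= 100 & pi$f0 <= 400))
    expect_true(all(pi$alpha >= 0 & pi$alpha <= 1))
    expect_true(all(pi$b_bb > 2000 & pi$b_bb <= 8000))
  }
})

test_that("auto-encoder training reduces the loss deterministically", {
  ds <- toy_dataset()
  cfg <- encoder_config(C = 16L, C_mel = 8L, n_conv = 2L, Dh = 12L)
  a1 <- train_autoencoder(ds, cfg, seed = 3, steps = 15, batch = 4, lr = 0.01)
  a2 <- train_autoencoder(ds, cfg, seed = 3, steps = 15, batch = 4, lr = 0.01)
  expect_identical(a1$curve, a2$curve)
  expect_identical(a1$speaker$proto, a2$speaker$proto)
  expect_lt(mean(tail(a1$curve, 3)), mean(head(a1$curve, 3)))
  # the fitted speaker parameters keep their invariants by construction
  for (j in 1:7) expect_true(neurovox:::is_unimodal(a1$speaker$proto[, j]))
  expect_s3_class(predict(a1, ds$trials[[1]]$spec), "speech_params")
  rec <- reconstruct(a1, ds$trials[[1]]$spec)
  expect_identical(dim(unclass(rec)), dim(unclass(ds$trials[[1]]$spec)))
})

test_that("training aborts with a diagnostic on non-finite losses", {
  ds <- toy_dataset()
  cfg <- encoder_config(C = 8L, C_mel = 4L, n_conv = 1L, Dh = 8L)
  bad <- ds$trials[ds$train][1:2]
  bad[[1L]]$spec[3, 5] <- NaN
  expect_error(train_autoencoder(bad, cfg, seed = 1, steps = 5, batch = 2),
               "diverged|NaN|Inf|missing")
})
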