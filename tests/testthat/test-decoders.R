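# Decoder backbones: shape contracts, causality, swin structure.

test_that("all backbones emit valid speech parameters with one frame per input frame", {
  x <- toy_ecog()
  T <- ecog_frames(x)
  for (bk in c("resnet3d", "swin3d", "lstm")) for (cz in c(TRUE, FALSE)) {
    st <- decoder_state(toy_decoder_cfg(bk, cz), seed = 5)
    out <- decode(x, st)
    expect_identical(n_frames(out), T)
    expect_silent(validate_speech_params(out))
  }
})

test_that("the LSTM backbone accepts arbitrary frame counts", {
  st <- decoder_state(toy_decoder_cfg("lstm", TRUE), grid = c(2L, 2L), seed = 1)
  x7 <- ecog_tensor(array(rnorm(7 * 4), c(7, 2, 2)))
  expect_identical(n_frames(decode(x7, st)), 7L)
})

test_that("causal variants pass the perturbation probe, non-causal variants fail it", {
  x <- toy_ecog()
  T <- ecog_frames(x)
  for (bk in c("resnet3d", "swin3d", "lstm")) {
    stc <- decoder_state(toy_decoder_cfg(bk, TRUE), seed = 5)
    stn <- decoder_state(toy_decoder_cfg(bk, FALSE), seed = 5)
    for (t in c(9L, 31L, T)) {
      expect_true(causality_probe(function(xx) decode(xx, stc), x, t, seed = t),
                  label = paste(bk, "causal probe at", t))
    }
    fails <- !vapply(c(9L, 31L), function(t)
      causality_probe(function(xx) decode(xx, stn), x, t, seed = t), TRUE)
    expect_true(any(fails), label = paste(bk, "non-causal detects future"))
  }
})

test_that("patch partition yields (T/2)(H/2)(W/2) tokens of 8 raw features", {
  arr <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  pp <- swin_patch_partition(arr)
  expect_identical(dim(pp$tokens), c(4L * 2L * 2L, 8L))
  expect_identical(pp$dims, c(4L, 2L, 2L))
  # token (1,1,1) holds exactly the first 2x2x2 block
  expect_setequal(pp$tokens[1, ], as.vector(arr[1:2, 1:2, 1:2]))
})

test_that("shifted windows connect tokens of adjacent unshifted windows", {
  dims <- c(4L, 4L, 4L)
  win <- c(2L, 2L, 2L)
  plain <- swin_windows(dims, win, shift = FALSE)
  shifted <- swin_windows(dims, win, shift = TRUE)
  # map each token to its unshifted window id
  wid <- integer(prod(dims))
  for (i in seq_along(plain)) wid[plain[[i]]] <- i
  spans <- vapply(shifted, function(g) length(unique(wid[g])), 1L)
  expect_gt(max(spans), 1)   # some shifted window mixes >= 2 plain windows
  expect_setequal(unlist(shifted), seq_len(prod(dims)))  # partition covers all
})

test_that("the causal attention mask never lets a token attend to its future", {
  tvec <- c(1L, 1L, 2L, 2L, 3L)
  M <- neurovox:::causal_mask(tvec)
  for (i in seq_along(tvec)) for (j in seq_along(tvec)) {
    expect_identical(is.infinite(M[i, j]), tvec[j] > tvec[i])
  }
})

test_that("decoder training is reproducible and its loss decreases", {
  ds <- toy_dataset()
  cfg <- toy_decoder_cfg("lstm", TRUE)
  d1 <- train_decoder(ds, cfg, seed = 7, steps = 12, batch = 4, lr = 0.01)
  d2 <- train_decoder(ds, cfg, seed = 7, steps = 12, batch = 4, lr = 0.01)
  expect_identical(d1$curve, d2$curve)
  expect_identical(d1$params$wo, d2$params$wo)
  expect_lt(mean(tail(d1$curve, 3)), mean(head(d1$curve, 3)))
})

test_that("masked electrodes are zero-filled and ignored", {
  x <- toy_ecog()
  x$valid_mask[3, 3] <- FALSE
  st <- decoder_state(toy_decoder_cfg("lstm", TRUE), seed = 2)
  base <- as.matrix(decode(x, st))
  x2 <- x
  x2$values[, 3, 3] <- 99   # content of an invalid electrode must not matter
  expect_identical(as.matrix(decode(x2, st)), base)
})
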