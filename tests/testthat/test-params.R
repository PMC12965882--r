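# Speech/speaker parameter containers, bandwidth relation, prototypes.

test_that("speaker parameter counts match the printed totals", {
  expect_identical(count_learnable_params("female"), 834L)
  expect_identical(count_learnable_params("male"), 1090L)
  # prototype subtotal M(N+1): 80 samples for 6 formant + 1 broadband filter
  s <- toy_speaker()
  expect_identical(length(s$proto), 560L)
  expect_identical(count_learnable_params("male") - count_learnable_params("female"),
                   512L - 256L)
  expect_error(count_learnable_params("child"))
})

test_that("bandwidth relation is piecewise linear and continuous at the threshold", {
  rel <- c(f_theta = 500, slope = 0.2, b0 = 100)
  expect_equal(bandwidth_from_center(400, rel), 100)
  expect_equal(bandwidth_from_center(500, rel), 100)
  expect_equal(bandwidth_from_center(1500, rel), 300)
  eps <- 1e-6
  expect_equal(bandwidth_from_center(500 + eps, rel), 100, tolerance = 1e-8)
  expect_error(bandwidth_from_center(400, c(500, 0.2, -1)))
  expect_error(bandwidth_from_center(-10, rel))
})

test_that("prototype filters interpolate their samples and expose exact half-power width", {
  M <- neurovox:::NV_M_PROTO
  xs <- seq(0, 8000, length.out = M)
  # symmetric triangle of half-height width w
  centre <- xs[40]
  w <- 1200
  tri <- pmax(0, 1 - abs(xs - centre) / w)
  pf <- prototype_filter_eval(tri, xs)
  expect_equal(pf$gain, tri)             # passes through the samples
  expect_equal(pf$f_proto, centre)
  # oracle: dense-grid scan for gain >= 1/sqrt(2)
  dense <- seq(0, 8000, by = 0.25)
  gd <- prototype_filter_eval(tri, dense)$gain
  span <- range(dense[gd >= 1 / sqrt(2)])
  expect_equal(pf$b_proto, diff(span), tolerance = 1e-3)
  expect_equal(pf$b_proto, 2 * w * (1 - 1 / sqrt(2)), tolerance = 1e-6)
  # out-of-range queries clamp to endpoint samples
  expect_equal(prototype_filter_eval(tri, c(-100, 9000))$gain, c(tri[1], tri[M]))
  expect_error(prototype_filter_eval(sin(seq(0, 20, length.out = M)) + 1, xs))
})

test_that("formant filter response peaks at f_c with the requested half-power width", {
  s <- toy_speaker()
  proto <- s$proto[, 1]
  f <- seq(0, 8000, by = 1)
  resp <- formant_filter_response(proto, f_c = 1000, bw = 200, amp = 0.7, f)
  expect_equal(max(resp), 0.7, tolerance = 1e-3)
  expect_equal(f[which.max(resp)], 1000, tolerance = 32)
  span <- range(f[resp >= max(resp) / sqrt(2)])
  expect_equal(diff(span), 200, tolerance = 8)
  expect_equal(formant_filter_response(proto, 1000, 200, 0, f), rep(0, length(f)))
  # bw = b_proto, f_c = f_proto reproduces amp * G exactly on the sample grid
  pf <- prototype_filter_eval(proto, numeric(0))
  xs <- seq(0, 8000, length.out = neurovox:::NV_M_PROTO)
  resp2 <- formant_filter_response(proto, pf$f_proto, pf$b_proto, 2, xs)
  expect_equal(resp2, 2 * proto, tolerance = 1e-9)
  expect_error(formant_filter_response(proto, 1000, -5, 1, f))
})

test_that("speech parameter container enforces its invariants", {
  p <- toy_params()
  expect_identical(ncol(as.matrix(p)), 18L)
  expect_identical(n_frames(p), 40L)
  rt <- speech_params_from_matrix(as.matrix(p))
  expect_equal(as.matrix(rt), as.matrix(p))
  bad <- p; bad$alpha[3] <- 1.4
  expect_error(validate_speech_params(bad), "alpha")
  bad2 <- p; bad2$b_bb[1] <- 1500
  expect_error(validate_speech_params(bad2), "2000")
  bad3 <- p; bad3$f0 <- bad3$f0[-1]
  expect_error(validate_speech_params(bad3), "frame count")
  bad4 <- p; bad4$formant_f[2, 3] <- 9000
  expect_error(validate_speech_params(bad4), "8000")
})

test_that("unimodal construction always yields a single peak of exactly 1", {
  set.seed(5)
  for (i in 1:25) {
    g <- neurovox:::unimodal_from_raw(rnorm(neurovox:::NV_M_PROTO, 0, 2))
    expect_true(neurovox:::is_unimodal(g))
    expect_equal(max(g), 1)
  }
})
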