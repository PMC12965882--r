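# The tape engine: every op's analytic gradient must match central finite
# differences on random inputs.

ad_check <- function(fun_tape, x, tol = 1e-5) {
  tape <- neurovox:::nv_tape()
  xn <- neurovox:::tp_leaf(tape, x)
  loss <- fun_tape(tape, xn)
  neurovox:::tp_backward(tape, loss)
  fd <- fd_gradient(function(xx) {
    tp2 <- neurovox:::nv_tape()
    fun_tape(tp2, neurovox:::tp_leaf(tp2, xx))$value
  }, x, h = 1e-6)
  expect_lt(max(abs(xn$grad - fd)) / max(abs(fd), 1e-8), tol)
}

test_that("elementwise, reduction and linear-algebra gradients match finite differences", {
  set.seed(1)
  x <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  v3 <- rnorm(3); b4 <- rnorm(4)
  tp <- neurovox:::nv_tape
  ops <- list(
    function(tape, a) neurovox:::tp_sum(tape, neurovox:::tp_mul(
      tape, neurovox:::tp_sigmoid(tape, a), neurovox:::tp_tanh(tape, a))),
    function(tape, a) {
      b <- neurovox:::tp_softplus(tape, a)
      neurovox:::tp_sum(tape, neurovox:::tp_add(
        tape, neurovox:::tp_log(tape, b), neurovox:::tp_sqrt(tape, b)))
    },
    function(tape, a) neurovox:::tp_sum(tape, neurovox:::tp_square(
      tape, neurovox:::tp_matmul(tape, a, neurovox:::tp_const(tape, W)))),
    function(tape, a) neurovox:::tp_sum(tape, neurovox:::tp_abs(
      tape, neurovox:::tp_add_bias(tape, neurovox:::tp_mul_rows(
        tape, a, neurovox:::tp_const(tape, v3)), neurovox:::tp_const(tape, b4)))),
    function(tape, a) {
      s <- neurovox:::tp_softmax_rows(tape, a)
      neurovox:::tp_sum(tape, neurovox:::tp_mul(tape, s, W[c(1, 2, 1), c(1, 2, 1, 2)]))
    },
    function(tape, a) neurovox:::tp_sum(tape, neurovox:::tp_square(
      tape, neurovox:::tp_layernorm_rows(
        tape, a, neurovox:::tp_const(tape, abs(b4) + 0.5),
        neurovox:::tp_const(tape, b4))))
  )
  for (op in ops) ad_check(op, x)
})

test_that("sequence ops (cumsum, rolling sums, framing, interpolation) differentiate", {
  set.seed(2)
  v <- rnorm(10)
  gs <- runif(6)
  Q <- rnorm(20, 0, 2)
  ad_check(function(tape, a) {
    cs <- neurovox:::tp_cumsum(tape, a)
    m <- neurovox:::tp_cbind(tape, list(neurovox:::tp_as_col(tape, cs),
                                        neurovox:::tp_as_col(tape, cs)))
    neurovox:::tp_sum(tape, neurovox:::tp_square(
      tape, neurovox:::tp_rollsum_cols(tape, m, 3L)))
  }, v)
  ad_check(function(tape, a) {
    u <- neurovox:::tp_upsample_hold(tape, a, 4L)
    neurovox:::tp_sum(tape, neurovox:::tp_sin(
      tape, neurovox:::tp_frame(tape, u, matrix(1:40, 8, 5))))
  }, v)
  ad_check(function(tape, a) {
    q <- neurovox:::tp_interp1(tape, neurovox:::tp_const(tape, c(0, .3, .8, 1, .6, .2)),
                               a, x0 = -2, dx = 1)
    neurovox:::tp_sum(tape, neurovox:::tp_square(tape, q))
  }, v)
  ad_check(function(tape, a) {
    q <- neurovox:::tp_interp1(tape, a, neurovox:::tp_const(tape, Q),
                               x0 = -2, dx = 1)
    neurovox:::tp_sum(tape, neurovox:::tp_square(tape, q))
  }, gs)
})

test_that("convolution gradients (causal/non-causal, strided, transposed) match finite differences", {
  set.seed(3)
  xc <- matrix(rnorm(2 * 6 * 3), 12, 3)
  wc <- matrix(rnorm(9 * 2), 9, 2)
  bc <- rnorm(2)
  for (cz in c(TRUE, FALSE)) for (st in c(1L, 2L)) {
    ad_check(function(tape, a) {
      neurovox:::tp_sum(tape, neurovox:::tp_square(tape, neurovox:::tp_conv1d(
        tape, a, neurovox:::tp_const(tape, wc), neurovox:::tp_const(tape, bc),
        B = 2L, T = 6L, k = 3L, causal = cz, stride = st)))
    }, xc)
  }
  ad_check(function(tape, a) {
    neurovox:::tp_sum(tape, neurovox:::tp_square(tape, neurovox:::tp_conv1d(
      tape, neurovox:::tp_const(tape, xc), a, NULL, B = 2L, T = 6L, k = 3L)))
  }, wc)
  xt <- matrix(rnorm(2 * 3 * 2), 6, 2)
  wt <- matrix(rnorm(4 * 2), 4, 2)
  for (cz in c(TRUE, FALSE)) {
    ad_check(function(tape, a) {
      neurovox:::tp_sum(tape, neurovox:::tp_square(tape, neurovox:::tp_tconv1d(
        tape, a, neurovox:::tp_const(tape, wt), neurovox:::tp_const(tape, rep(0.1, 2)),
        B = 2L, T_in = 3L, r = 2L, causal = cz)))
    }, xt)
  }
})

test_that("constant subgraphs are skipped in the backward sweep", {
  tape <- neurovox:::nv_tape()
  a <- neurovox:::tp_const(tape, matrix(1:4, 2))
  b <- neurovox:::tp_square(tape, a)
  expect_true(b$const)
  le <- neurovox:::tp_leaf(tape, matrix(1, 2, 2))
  s <- neurovox:::tp_sum(tape, neurovox:::tp_mul(tape, le, b))
  expect_false(s$const)
  neurovox:::tp_backward(tape, s)
  expect_equal(le$grad, matrix(c(1, 4, 9, 16), 2, 2))
})
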