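# Shared neural-network machinery: parameter initialization, the Adam
# optimizer, and the prediction head that maps backbone features to the 18
# speech parameters (reused by the speech encoder and all ECoG decoders).

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# flatten/unflatten nested named lists of arrays (model states)
params_flatten <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]])) out <- c(out, params_flatten(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

#' Adam optimizer state
#' @param params Named list of numeric arrays.
#' @param lr Learning rate (default 1e-3).
#' @param beta1,beta2 Moment decay rates (defaults 0.9, 0.999).
#' @param eps Numerical floor.
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

# one Adam update; returns list(params, opt)
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(params = params, opt = opt)
}

# create leaf nodes for every array in a flat parameter list
leafify <- function(tape, params) lapply(params, function(p) tp_leaf(tape, p))

# read accumulated gradients back from leaf nodes (missing -> zeros)
collect_grads <- function(nodes) {
  lapply(nodes, function(nd) if (is.null(nd$grad)) nd$value * 0 else nd$grad)
}

# ---- frequency ranges for the de-normalized parameter channels ---------

#' Frequency ranges used to de-normalize sigmoid channel outputs
#'
#' Sigmoid-activated network channels in `[0, 1]` are scaled to these
#' `[f_min, f_max]` ranges (Hz) for the frequency-valued parameters; the
#' broadband bandwidth maps to `(2000, 8000]`.
#' @param profile Voice profile (sets the pitch range).
#' @return 9 x 2 matrix with rows f0, f1..f6, f_bb, b_bb.
#' @export
nv_freq_ranges <- function(profile = c("female", "male")) {
  profile <- match.arg(profile)
  f0r <- if (profile == "female") c(100, 400) else c(50, 250)
  rbind(f0 = f0r,
        f1 = c(200, 1000), f2 = c(500, 3000), f3 = c(1200, 4000),
        f4 = c(2000, 5000), f5 = c(3000, 7000), f6 = c(4000, 8000),
        f_bb = c(1000, 8000), b_bb = c(2000 + 1e-6, 8000))
}

#' De-normalize a unit-interval value to a frequency range
#' @param u Values in `[0, 1]`.
#' @param range Numeric `c(f_min, f_max)`.
#' @return `f_min + u * (f_max - f_min)`, Hz.
#' @export
denormalize_frequency <- function(u, range) {
  if (any(u < 0 | u > 1)) stop("denormalize_frequency: u must lie in [0, 1]")
  range[1L] + u * (range[2L] - range[1L])
}

# ---- shared prediction head --------------------------------------------

# The head applies a temporal convolution (kernel 3, causal flag honored)
# followed by a two-layer per-frame MLP, then channelwise activations:
# sigmoid + de-normalization for frequency channels, softplus for
# amplitudes and loudness, sigmoid for the voicing weight.

head_init <- function(D, Dh = 32L, profile = "female") {
  list(wc = he_init(7L * D, Dh), bc = numeric(Dh),
       w1 = he_init(Dh, Dh), b1 = numeric(Dh),
       w2 = he_init(Dh, 18L), b2 = numeric(18L),
       wlin = he_init(D, 18L) * 0.3,
       profile = profile)
}

# sigmoid channel layout within the raw 18 outputs (canonical order)
HEAD_SIG_COLS <- c(1:7, 14L, 15L, 17L)    # f0, f1..f6, f_bb, b_bb, alpha
HEAD_SOFT_COLS <- c(8:13, 16L, 18L)       # a1..a6, a_bb, loudness

head_ranges <- function(profile) {
  fr <- nv_freq_ranges(profile)
  lo <- c(fr[, 1L], 0)       # alpha min 0
  hi <- c(fr[, 2L], 1)       # alpha max 1
  list(lo = lo, hi = hi)
}

# feat: (B*T) x D node -> raw (B*T) x 18 node (pre-activation).  The MLP
# branch is complemented by a direct linear readout so near-linear
# feature-to-parameter relationships can be represented exactly.
head_raw <- function(tape, nodes, feat, B, T, causal = TRUE) {
  h <- tp_relu(tape, tp_conv1d(tape, feat, nodes$wc, nodes$bc, B, T, 7L, causal))
  h <- tp_relu(tape, tp_add_bias(tape, tp_matmul(tape, h, nodes$w1), nodes$b1))
  mlp <- tp_add_bias(tape, tp_matmul(tape, h, nodes$w2), nodes$b2)
  tp_add(tape, mlp, tp_matmul(tape, feat, nodes$wlin))
}

# feat -> constrained parameter matrix node (canonical order)
head_forward <- function(tape, nodes, feat, B, T, causal = TRUE) {
  head_activations(tape, head_raw(tape, nodes, feat, B, T, causal),
                   nodes$profile)
}

# raw (B*T) x 18 -> constrained parameter matrix node (canonical order)
head_activations <- function(tape, raw, profile) {
  rg <- head_ranges(if (is.null(profile)) "female" else profile)
  sig <- tp_sigmoid(tape, tp_cols(tape, raw, HEAD_SIG_COLS))
  sig <- tp_add_bias(tape, tp_mul_cols(tape, sig, tp_const(tape, rg$hi - rg$lo)),
                     tp_const(tape, rg$lo))
  soft <- tp_softplus(tape, tp_cols(tape, raw, HEAD_SOFT_COLS))
  both <- tp_cbind(tape, list(sig, soft))
  # undo the column split: both = [sig(10) | soft(8)] -> canonical order
  perm <- integer(18L)
  perm[HEAD_SIG_COLS] <- seq_along(HEAD_SIG_COLS)
  perm[HEAD_SOFT_COLS] <- length(HEAD_SIG_COLS) + seq_along(HEAD_SOFT_COLS)
  tp_cols(tape, both, perm)
}

# Per-channel affine normalization constants for the training losses:
# frequency-valued channels are mapped to [0, 1] by their de-normalization
# ranges so that all 18 channels are commensurate and the printed loss
# weights are meaningful; amplitudes, loudness and the voicing weight are
# already order 1 and pass through unchanged.
param_norm_consts <- function(profile = "female") {
  fr <- nv_freq_ranges(profile)
  lo <- numeric(18L); sc <- rep(1, 18L)
  freq_cols <- c(1:7, 14L, 15L)
  lo[freq_cols] <- fr[, 1L]
  sc[freq_cols] <- fr[, 2L] - fr[, 1L]
  list(lo = lo, sc = sc)
}

# normalize a (B*T) x 18 parameter matrix (numeric or node) channelwise
normalize_params_num <- function(m, nc) {
  sweep(sweep(m, 2L, nc$lo), 2L, nc$sc, "/")
}

tp_normalize_params <- function(tape, pred, nc) {
  shifted <- tp_add_bias(tape, pred, tp_const(tape, -nc$lo))
  tp_mul_cols(tape, shifted, tp_const(tape, 1 / nc$sc))
}

# parameter-matrix node -> the node list consumed by synth_forward
pred_to_pn <- function(tape, pred) {
  list(f0 = tp_as_vec(tape, tp_cols(tape, pred, 1L)),
       ff = tp_cols(tape, pred, 2:7),
       fa = tp_cols(tape, pred, 8:13),
       f_bb = tp_as_vec(tape, tp_cols(tape, pred, 14L)),
       b_bb = tp_as_vec(tape, tp_cols(tape, pred, 15L)),
       a_bb = tp_as_vec(tape, tp_cols(tape, pred, 16L)),
       alpha = tp_as_vec(tape, tp_cols(tape, pred, 17L)),
       loudness = tp_as_vec(tape, tp_cols(tape, pred, 18L)))
}
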