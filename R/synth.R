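# Differentiable source-filter speech synthesizer.
#
# The voice pathway drives a harmonic excitation (sum of up to 80 equal-
# amplitude harmonics of the pitch, synthesized at audio rate with the phase
# accumulated in cycles) through six formant filters; the noise pathway
# filters seeded Gaussian white noise through a broadband filter plus the
# same formant filters.  The two magnitude spectrograms are soft-mixed by
# the voicing weight, scaled by loudness, and offset by the learned
# background spectrum:
#
#   S_hat[t, f] = L[t] * (alpha[t] V[t, f] + (1 - alpha[t]) U[t, f]) + B[f]
#
# Everything is built on tape operations, so gradients flow to all 18
# per-frame speech parameters and all speaker parameters.

.nv_cache <- new.env(parent = emptyenv())

# per-K constants: frequency grid, Hann window, DFT matrices
synth_consts <- function(K) {
  key <- paste0("K", K)
  if (is.null(.nv_cache[[key]])) {
    win <- 2L * K
    n <- seq_len(win) - 1L
    k <- seq_len(K) - 1L
    ang <- 2 * pi * outer(n, k) / win
    .nv_cache[[key]] <- list(
      f_grid = spec_freqs(K), win = win, w = hann(win),
      C = cos(ang), S = -sin(ang), scale = 2 / sum(hann(win))
    )
  }
  .nv_cache[[key]]
}

# Number of unaliased harmonics per sample: k * f0 <= f_max, capped.
harmonic_count <- function(f0_up, n_harm, f_max) {
  n <- pmin(floor(f_max / pmax(f0_up, 1e-12)), n_harm)
  n[f0_up <= 0] <- 0
  n
}

# Direct O(n_harm) evaluation of the harmonic stack and its phase
# derivative; the independent reference for the closed form below.
harmonic_bank_direct <- function(phi, f0_up, n_harm, f_max = NV_FMAX) {
  n <- harmonic_count(f0_up, n_harm, f_max)
  h <- numeric(length(phi))
  d <- numeric(length(phi))
  for (k in seq_len(n_harm)) {
    m <- n >= k
    if (!any(m)) break
    h <- h + m * sin(2 * pi * k * phi)
    d <- d + m * (2 * pi * k) * cos(2 * pi * k * phi)
  }
  list(h = h, dphi = d)
}

# Closed-form Dirichlet-kernel evaluation of sum_{k=1}^{n} sin(k * theta)
# and sum k cos(k theta), with a direct-sum fallback near theta = 2 pi m
# where the geometric-series denominators degenerate.
harmonic_bank_eval <- function(phi, n) {
  theta <- 2 * pi * (phi %% 1)
  z <- complex(modulus = 1, argument = theta)
  den <- 1 - z
  small <- Mod(den) < 1e-3 | n == 0
  h <- numeric(length(phi))
  d <- numeric(length(phi))
  ok <- !small
  if (any(ok)) {
    zn <- complex(modulus = 1, argument = theta[ok] * n[ok])
    zok <- z[ok]
    s1 <- zok * (zn - 1) / (zok - 1)
    h[ok] <- Im(s1)
    s2 <- zok * (1 - (n[ok] + 1) * zn + n[ok] * zn * zok) / den[ok]^2
    d[ok] <- 2 * pi * Re(s2)
  }
  idx <- which(small & n > 0)
  if (length(idx)) {
    for (k in seq_len(max(n[idx]))) {
      m <- n[idx] >= k
      h[idx] <- h[idx] + m * sin(k * theta[idx])
      d[idx] <- d[idx] + m * (2 * pi * k) * cos(k * theta[idx])
    }
  }
  list(h = h, dphi = d)
}

# custom tape op: sum of masked harmonics of an accumulated phase (cycles)
tp_harmonic_bank <- function(tape, phi, f0_up, n_harm, f_max) {
  n <- harmonic_count(f0_up, n_harm, f_max)
  hb <- harmonic_bank_eval(phi$value, n)
  .tp_node(tape, hb$h, list(phi), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * hb$dphi)
  })
}

tp_pad_zeros <- function(tape, a, npad) {
  n <- length(a$value)
  .tp_node(tape, c(a$value, numeric(npad)), list(a), function(nd) {
    .acc(nd$parents[[1L]], nd$grad[seq_len(n)])
  })
}

# STFT framing of B concatenated trials of T*hop samples each; windows are
# zero beyond each trial's end.  Backward is a block overlap-add.
tp_frame_stft <- function(tape, x, T, B, win, hop) {
  T <- as.integer(T); B <- as.integer(B)
  win <- as.integer(win); hop <- as.integer(hop)
  q <- win %/% hop
  blk <- T * hop
  idx1 <- stft_index(blk, win)
  idx1[idx1 > blk] <- 0L
  aug <- c(x$value, 0)
  naug <- length(x$value) + 1L
  val <- matrix(0, B * T, win)
  for (b in seq_len(B)) {
    ib <- idx1
    ib[ib == 0L] <- naug - (b - 1L) * blk
    val[((b - 1L) * T + 1L):(b * T), ] <- matrix(aug[ib + (b - 1L) * blk], T, win)
  }
  .tp_node(tape, val, list(x), function(nd) {
    g <- nd$grad
    gx <- matrix(0, B * (T + q - 1L), hop)
    base <- rep((seq_len(B) - 1L) * (T + q - 1L), each = T)
    tt <- rep(seq_len(T), times = B)
    for (c in seq_len(q)) {
      rows <- base + tt + (c - 1L)
      gx[rows, ] <- gx[rows, ] + g[, ((c - 1L) * hop + 1L):(c * hop), drop = FALSE]
    }
    keep <- rep((seq_len(B) - 1L) * (T + q - 1L), each = T) + rep(seq_len(T), B)
    .acc(nd$parents[[1L]], as.vector(t(gx[keep, , drop = FALSE])))
  })
}

# magnitude STFT of a (batched) audio-rate tape vector -> (B*T) x K node;
# windows never read across trial boundaries (out-of-trial samples are 0)
tp_stft_mag <- function(tape, x, T, K, B = 1L) {
  cst <- synth_consts(K)
  fr <- tp_frame_stft(tape, x, T, B, cst$win, NV_HOP)
  fr <- tp_mul(tape, fr, matrix(cst$w, B * T, cst$win, byrow = TRUE))
  re <- tp_matmul(tape, fr, tp_const(tape, cst$C))
  im <- tp_matmul(tape, fr, tp_const(tape, cst$S))
  mag <- tp_sqrt(tape, tp_addc(tape, tp_add(tape, tp_square(tape, re),
                                            tp_square(tape, im)), 1e-12))
  tp_scale(tape, mag, cst$scale)
}

# harmonic excitation spectrogram from a pitch node (B trials x T frames)
tp_harmonics <- function(tape, f0, T, K, n_harm = NV_N_HARMONICS, B = 1L) {
  f0_up_v <- rep(f0$value, each = NV_HOP)
  f0_up <- tp_upsample_hold(tape, f0, NV_HOP)
  phi <- tp_cumsum_blocks(tape, tp_scale(tape, f0_up, 1 / NV_FS_AUDIO),
                          T * NV_HOP)
  h <- tp_harmonic_bank(tape, phi, f0_up_v, n_harm, NV_FMAX)
  tp_stft_mag(tape, h, T, K, B)
}

# one shifted/scaled filter response: gain[t, f] with per-frame fc, bw, amp
tp_filter_response <- function(tape, proto_col, fc, bw, amp, b_proto, f_proto, K) {
  cst <- synth_consts(K)
  inv <- tp_div(tape, tp_const(tape, 1), bw)
  r <- tp_scale(tape, inv, b_proto)                     # b_proto / bw, per frame
  p1 <- tp_matmul(tape, tp_as_col(tape, r),
                  tp_const(tape, matrix(cst$f_grid, 1L)))
  rc <- tp_mul(tape, r, fc)
  pos <- tp_addc(tape, tp_add_rowvec(tape, p1, tp_neg(tape, rc)), f_proto)
  gain <- tp_interp1(tape, proto_col, pos, x0 = 0,
                     dx = NV_FMAX / (NV_M_PROTO - 1L))
  tp_mul_rows(tape, gain, amp)
}

# speaker raw leaves -> constrained speaker nodes (tape mirror of
# speaker_from_raw); also returns numeric prototype peak/half-power data
speaker_nodes_from_raw <- function(tape, raw) {
  M <- NV_M_PROTO
  L <- lower.tri(matrix(0, M, M), diag = TRUE) + 0
  s <- tp_softplus(tape, raw$proto_raw)
  up <- tp_matmul(tape, tp_const(tape, L), s)
  dn <- tp_matmul(tape, tp_const(tape, t(L)), s)
  g <- tp_pmin2(tape, up, dn)
  pk <- tp_colmax(tape, g)
  proto <- tp_mul_cols(tape, g, tp_div(tape, tp_const(tape, 1), pk))
  bwsig <- tp_sigmoid(tape, raw$bw_raw)
  f_theta <- tp_scale(tape, tp_cols(tape, bwsig, 1L), 1500)
  slope <- tp_scale(tape, tp_cols(tape, bwsig, 2L), 0.12)
  b0 <- tp_addc(tape, tp_scale(tape, tp_cols(tape, bwsig, 3L), 160), 40)
  background <- tp_softplus(tape, raw$bg_raw)
  list(proto = proto, f_theta = f_theta, slope = slope, b0 = b0,
       background = background)
}

# wrap constrained speaker values as constant speaker nodes
speaker_nodes_const <- function(tape, s) {
  list(proto = tp_const(tape, s$proto),
       f_theta = tp_const(tape, matrix(s$bw_relation[, 1L], ncol = 1L)),
       slope = tp_const(tape, matrix(s$bw_relation[, 2L], ncol = 1L)),
       b0 = tp_const(tape, matrix(s$bw_relation[, 3L], ncol = 1L)),
       background = tp_const(tape, s$background))
}

# wrap speech params as tape nodes (const or leaf)
params_nodes <- function(tape, p, leaf = FALSE) {
  mk <- if (leaf) tp_leaf else tp_const
  list(f0 = mk(tape, p$f0), ff = mk(tape, p$formant_f), fa = mk(tape, p$formant_a),
       f_bb = mk(tape, p$f_bb), b_bb = mk(tape, p$b_bb), a_bb = mk(tape, p$a_bb),
       alpha = mk(tape, p$alpha), loudness = mk(tape, p$loudness))
}

scalar_at <- function(tape, mat_node, i) {
  tp_as_vec(tape, tp_gather_rows(tape, mat_node, i))
}

# Full synthesizer forward pass on a tape.
#
# pn: speech-parameter nodes; sn: speaker nodes; noise_mag: numeric T x K
# noise-excitation magnitudes (constant w.r.t. all parameters).
# Returns nodes for the final spectrogram and both pathway components.
synth_forward <- function(tape, pn, sn, T, K, noise_mag,
                          n_harm = NV_N_HARMONICS, B = 1L) {
  protov <- sn$proto$value
  H <- tp_harmonics(tape, pn$f0, T, K, n_harm, B = B)
  Fv <- NULL
  for (i in seq_len(NV_N_FORMANTS)) {
    pf <- prototype_filter_eval(protov[, i], numeric(0))
    fc <- tp_as_vec(tape, tp_cols(tape, pn$ff, i))
    am <- tp_as_vec(tape, tp_cols(tape, pn$fa, i))
    ft <- scalar_at(tape, sn$f_theta, i)
    sl <- scalar_at(tape, sn$slope, i)
    b0 <- scalar_at(tape, sn$b0, i)
    # bandwidth relation: b0 + slope * max(fc - f_theta, 0), continuous in fc
    bw <- tp_add(tape, tp_mul(tape, sl,
                              tp_relu(tape, tp_sub(tape, fc, ft))), b0)
    proto_col <- tp_as_vec(tape, tp_cols(tape, sn$proto, i))
    Fi <- tp_filter_response(tape, proto_col, fc, bw, am,
                             pf$b_proto, pf$f_proto, K)
    Fv <- if (is.null(Fv)) Fi else tp_add(tape, Fv, Fi)
  }
  pfu <- prototype_filter_eval(protov[, 7L], numeric(0))
  proto_bb <- tp_as_vec(tape, tp_cols(tape, sn$proto, 7L))
  Fbb <- tp_filter_response(tape, proto_bb, pn$f_bb, pn$b_bb, pn$a_bb,
                            pfu$b_proto, pfu$f_proto, K)
  Fu <- tp_add(tape, Fbb, Fv)
  V <- tp_mul(tape, Fv, H)
  U <- tp_mul(tape, Fu, tp_const(tape, noise_mag))
  one_minus <- tp_addc(tape, tp_neg(tape, pn$alpha), 1)
  mix <- tp_add(tape, tp_mul_rows(tape, V, pn$alpha),
                tp_mul_rows(tape, U, one_minus))
  S <- tp_add_bias(tape, tp_mul_rows(tape, mix, pn$loudness), sn$background)
  list(S = S, V = V, U = U, H = H, Fv = Fv, Fu = Fu)
}

# ---- numeric (user-facing) wrappers ------------------------------------

#' Harmonic excitation spectrogram for a pitch trajectory
#'
#' The excitation is the sum of up to `n_harmonics` equal-amplitude
#' harmonics of the pitch, synthesized at 16 kHz with the phase accumulated
#' in cycles; harmonics above 8000 Hz are zeroed, and frames with zero pitch
#' are silent.  The magnitude spectrogram is taken at 125 frames/s.
#' @param f0 Pitch per frame, Hz (nonnegative).
#' @param K Frequency bins.
#' @param n_harmonics Number of harmonics (default 80).
#' @return `nv_spectrogram`, `length(f0)` frames.
#' @export
harmonic_excitation <- function(f0, K = 256L, n_harmonics = NV_N_HARMONICS) {
  if (any(f0 < 0)) stop("harmonic_excitation: f0 must be nonnegative")
  tape <- nv_tape()
  H <- tp_harmonics(tape, tp_const(tape, f0), length(f0), K, n_harmonics)
  nv_spectrogram(H$value)
}

#' Noise-excitation magnitude spectrogram
#'
#' Magnitude STFT of seeded stationary Gaussian white noise sampled in the
#' time domain.
#' @param T Frames.
#' @param K Frequency bins.
#' @param seed Integer seed; the same seed reproduces the same excitation.
#' @export
noise_excitation <- function(T, K = 256L, seed = 0L) {
  n <- with_seed(seed, stats::rnorm(T * NV_HOP))
  unclass(stft_mag(n, K))
}

#' Voiced spectrogram component (formant-filtered harmonic excitation)
#' @param p `speech_params`.
#' @param s `speaker_params`.
#' @return `nv_spectrogram`.
#' @export
voice_component <- function(p, s) {
  validate_speech_params(p)
  K <- s$K
  tape <- nv_tape()
  pn <- params_nodes(tape, p)
  sn <- speaker_nodes_const(tape, s)
  out <- synth_forward(tape, pn, sn, n_frames(p), K,
                       matrix(0, n_frames(p), K))
  nv_spectrogram(out$V$value)
}

#' Unvoiced spectrogram component (filtered white noise)
#' @param p `speech_params`.
#' @param s `speaker_params`.
#' @param seed Seed for the noise excitation.
#' @return `nv_spectrogram`.
#' @export
unvoice_component <- function(p, s, seed = 0L) {
  validate_speech_params(p)
  K <- s$K
  tape <- nv_tape()
  pn <- params_nodes(tape, p)
  sn <- speaker_nodes_const(tape, s)
  out <- synth_forward(tape, pn, sn, n_frames(p), K,
                       noise_excitation(n_frames(p), K, seed))
  nv_spectrogram(out$U$value)
}

#' Synthesize a magnitude spectrogram from speech and speaker parameters
#'
#' @param p `speech_params` trajectory (T frames x 18 parameters).
#' @param s `speaker_params`.
#' @param seed Seed for the stochastic noise excitation; the voiced pathway
#'   is deterministic.
#' @return `nv_spectrogram` (T frames x K bins).
#' @export
synthesize <- function(p, s, seed = 0L) {
  validate_speech_params(p)
  K <- s$K
  tape <- nv_tape()
  pn <- params_nodes(tape, p)
  sn <- speaker_nodes_const(tape, s)
  out <- synth_forward(tape, pn, sn, n_frames(p), K,
                       noise_excitation(n_frames(p), K, seed))
  nv_spectrogram(out$S$value)
}
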