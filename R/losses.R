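# Training objectives: modified multi-scale spectral (MSS) loss, STOI+
# intelligibility metric and its negative as a loss, parameter supervision
# loss, reference loss, and the weighted totals used for auto-encoder and
# ECoG-decoder training.  Each loss has a plain numeric form and a tape
# form used during training; a shared helper guarantees both use the same
# constants.

#' Default loss weights
#'
#' `lambda1` scales the STOI loss, `lambda2` the supervision loss and
#' `lambda3` the reference loss.  `beta` holds the four formant supervision
#' weights, `ref` the 18 per-parameter reference-loss weights in canonical
#' parameter order.
#' @return Named list of weights.
#' @export
loss_weights <- function() {
  list(
    lambda1 = 1.2, lambda2 = 0.1, lambda3 = 1,
    beta = c(0.1, 0.06, 0.03, 0.02),
    ref = c(f0 = 0.4,
            f1 = 3, f2 = 1.8, f3 = 1.2, f4 = 0.9, f5 = 0.6, f6 = 0.3,
            a1 = 4, a2 = 2.4, a3 = 1.2, a4 = 0.9, a5 = 0.6, a6 = 0.3,
            f_bb = 10, b_bb = 4, a_bb = 4,
            alpha = 1.8, loudness = 1.5)
  )
}

# log floor: a small fraction of the joint dynamic range
mss_floor <- function(x, y) max(1e-6 * max(max(x), max(y)), 1e-12)

#' Modified multi-scale spectral loss
#'
#' `L(x, y) = ||x - y||_1 + ||log x - log y||_1` evaluated on the linear
#' spectrogram and on its Mel-scale reduction, then summed.  Logs are taken
#' on values floored at 1e-6 of the joint dynamic range.
#' @param S_hat,S Same-shape nonnegative magnitude matrices.
#' @param n_mels Mel bands for the Mel-scale term (default 80).
#' @return Nonnegative scalar, 0 iff the spectrograms are equal.
#' @export
mss_loss <- function(S_hat, S, n_mels = 80L) {
  x <- unclass(as.matrix(S_hat)); y <- unclass(as.matrix(S))
  if (!all(dim(x) == dim(y))) stop("mss_loss: shape mismatch")
  l1 <- function(a, b) {
    eps <- mss_floor(a, b)
    sum(abs(a - b)) + sum(abs(log(pmax(a, eps)) - log(pmax(b, eps))))
  }
  fb <- t(mel_filterbank(n_mels, ncol(x)))
  l1(x, y) + l1(x %*% fb, y %*% fb)
}

#' One-third octave band decomposition of a spectrogram
#'
#' Groups DFT bins into 15 one-third octave bands with the lowest centre
#' frequency at 150 Hz (highest centre ~4.3 kHz * 2^(-1/6)); band edges are
#' rounded to the nearest bin (ties downward).  Band norm
#' `X_j(m) = sqrt(sum_k |x(k, m)|^2)` over the band's bins.
#' @param spec Frames x K nonnegative magnitude matrix.
#' @param f_max Upper frequency of the grid, Hz.
#' @return List with `k1`, `k2` (per-band bin edges, 1-based, upper
#'   exclusive), `centres` (Hz) and `norms` (frames x 15).
#' @export
octave_band_norms <- function(spec, f_max = NV_FMAX) {
  x <- unclass(as.matrix(spec))
  K <- ncol(x)
  J <- 15L
  centres <- 150 * 2^((seq_len(J) - 1L) / 3)
  if (f_max < max(centres) * 2^(1 / 6))
    stop("octave_band_norms: frequency range must reach ~4.3 kHz")
  df <- f_max / K
  round_half_down <- function(v) ceiling(v - 0.5)
  k1 <- round_half_down(centres * 2^(-1 / 6) / df) + 1L
  k2 <- round_half_down(centres * 2^(1 / 6) / df) + 1L
  if (any(k2 <= k1))
    stop("octave_band_norms: spectrogram too coarse to resolve the lowest band")
  norms <- matrix(0, nrow(x), J)
  for (j in seq_len(J)) {
    norms[, j] <- sqrt(rowSums(x[, k1[j]:(k2[j] - 1L), drop = FALSE]^2))
  }
  list(k1 = k1, k2 = k2, centres = centres, norms = norms)
}

# indicator matrix K x 15 used by the tape version of the band analysis
octave_band_matrix <- function(K, f_max = NV_FMAX) {
  bd <- octave_band_norms(matrix(0, 1L, K), f_max)
  ind <- matrix(0, K, 15L)
  for (j in 1:15) ind[bd$k1[j]:(bd$k2[j] - 1L), j] <- 1
  ind
}

#' STOI+ intelligibility metric
#'
#' Average Pearson correlation between 30-frame one-third-octave band
#' envelope segments of two spectrograms; unlike original STOI there is no
#' clipping or normalization, so the value spans `[-1, 1]`.  Segments with
#' zero variance contribute 0.
#' @param x,y Same-shape magnitude matrices with at least 30 frames.
#' @param N Envelope segment length in frames (default 30).
#' @return Scalar in `[-1, 1]`.
#' @export
stoi_plus <- function(x, y, N = 30L) {
  xm <- unclass(as.matrix(x)); ym <- unclass(as.matrix(y))
  if (!all(dim(xm) == dim(ym))) stop("stoi_plus: shape mismatch")
  if (nrow(xm) < N) stop("stoi_plus: need at least ", N, " frames")
  X <- octave_band_norms(xm)$norms
  Y <- octave_band_norms(ym)$norms
  roll <- function(M) {
    cs <- rbind(0, apply(M, 2L, cumsum))
    cs[(N + 1L):nrow(cs), , drop = FALSE] - cs[1L:(nrow(cs) - N), , drop = FALSE]
  }
  Sx <- roll(X); Sy <- roll(Y)
  Sxx <- roll(X^2); Syy <- roll(Y^2); Sxy <- roll(X * Y)
  num <- N * Sxy - Sx * Sy
  den2 <- (N * Sxx - Sx^2) * (N * Syy - Sy^2)
  d <- ifelse(den2 > 1e-14, num / sqrt(pmax(den2, 1e-14)), 0)
  mean(d)
}

#' Supervision loss on pitch and the first four formant frequencies
#'
#' Sum of squared errors over frames for the pitch plus the weighted sums
#' for formants 1-4 (weights `beta`); formants 5 and 6 are unsupervised.
#' @param pred `speech_params` (or frames x 18 matrix) prediction.
#' @param ref_f0 Reference pitch series, Hz.
#' @param ref_formants Frames x 4 reference formant frequencies, Hz.
#' @param beta Length-4 weights (default the package defaults).
#' @export
supervision_loss <- function(pred, ref_f0, ref_formants,
                             beta = loss_weights()$beta) {
  m <- if (inherits(pred, "speech_params")) as.matrix(pred) else as.matrix(pred)
  ref_formants <- as.matrix(ref_formants)
  if (nrow(m) != length(ref_f0) || nrow(ref_formants) != length(ref_f0))
    stop("supervision_loss: frame counts differ")
  out <- sum((m[, 1L] - ref_f0)^2)
  for (i in 1:4) out <- out + beta[i] * sum((m[, 1L + i] - ref_formants[, i])^2)
  out
}

#' Reference loss over all 18 speech parameters
#'
#' `sum_j lambda_j ||C_pred[j] - C_ref[j]||^2` with the per-parameter
#' weights of [loss_weights()].
#' @param pred,ref `speech_params` or frames x 18 matrices.
#' @param weights Named length-18 weight vector in canonical order.
#' @export
reference_loss <- function(pred, ref, weights = loss_weights()$ref) {
  a <- as.matrix(pred); b <- as.matrix(ref)
  if (!all(dim(a) == dim(b))) stop("reference_loss: shape mismatch")
  sum(colSums((a - b)^2) * as.numeric(weights))
}

#' Auto-encoder training objective
#'
#' `L_MSS + lambda1 * (-STOI+) + lambda2 * L_supervision`.
#' @param S_hat,S Reconstructed and reference spectrograms.
#' @param pred Predicted `speech_params`.
#' @param ref_f0,ref_formants Supervision references (pitch, formants 1-4).
#' @param w Loss weights, see [loss_weights()].
#' @export
autoencoder_total <- function(S_hat, S, pred, ref_f0, ref_formants,
                              w = loss_weights()) {
  mss_loss(S_hat, S) - w$lambda1 * stoi_plus(S_hat, S) +
    w$lambda2 * supervision_loss(pred, ref_f0, ref_formants, w$beta)
}

#' ECoG-decoder training objective
#'
#' The auto-encoder objective plus `lambda3` times the reference loss
#' against guidance speech parameters.
#' @param S_hat,S Decoded and reference spectrograms.
#' @param pred Decoded `speech_params`.
#' @param ref_f0,ref_formants Supervision references.
#' @param guidance Reference `speech_params` (from the trained speech
#'   encoder, or ground truth on synthetic data).
#' @param w Loss weights.
#' @export
decoder_total <- function(S_hat, S, pred, ref_f0, ref_formants, guidance,
                          w = loss_weights()) {
  autoencoder_total(S_hat, S, pred, ref_f0, ref_formants, w) +
    w$lambda3 * reference_loss(pred, guidance, w$ref)
}

# ---- tape versions ------------------------------------------------------

# MSS loss node; S const numeric, S_hat node
tp_mss <- function(tape, S_hat, S, fb_t, eps = NULL) {
  if (is.null(eps)) eps <- mss_floor(S_hat$value, S)
  l1 <- function(a_node, b_mat, eps) {
    lin <- tp_sum(tape, tp_abs(tape, tp_sub(tape, a_node, b_mat)))
    la <- tp_log(tape, tp_pmax_const(tape, a_node, eps))
    lg <- tp_sum(tape, tp_abs(tape, tp_sub(tape, la, log(pmax(b_mat, eps)))))
    tp_add(tape, lin, lg)
  }
  Sm_hat <- tp_matmul(tape, S_hat, tp_const(tape, fb_t))
  Sm <- S %*% fb_t
  eps_m <- mss_floor(Sm_hat$value, Sm)
  tp_add(tape, l1(S_hat, S, eps), l1(Sm_hat, Sm, eps_m))
}

# STOI+ node for one trial; y const numeric
tp_stoi <- function(tape, x_node, y, band_ind, N = 30L) {
  sq <- tp_square(tape, x_node)
  bandE <- tp_matmul(tape, sq, tp_const(tape, band_ind))
  X <- tp_sqrt(tape, tp_addc(tape, bandE, 1e-14))
  Y <- sqrt(pmax((y^2) %*% band_ind, 0) + 1e-14)
  Sx <- tp_rollsum_cols(tape, X, N)
  Sxx <- tp_rollsum_cols(tape, tp_square(tape, X), N)
  Sxy <- tp_rollsum_cols(tape, tp_mul(tape, X, Y), N)
  Syv <- rbind(0, apply(Y, 2L, cumsum))
  Sy <- Syv[(N + 1L):nrow(Syv), , drop = FALSE] - Syv[1L:(nrow(Syv) - N), , drop = FALSE]
  Syy0 <- rbind(0, apply(Y^2, 2L, cumsum))
  Syy <- Syy0[(N + 1L):nrow(Syy0), , drop = FALSE] - Syy0[1L:(nrow(Syy0) - N), , drop = FALSE]
  num <- tp_sub(tape, tp_scale(tape, Sxy, N), tp_mul(tape, Sx, Sy))
  vx <- tp_pmax_const(tape, tp_sub(tape, tp_scale(tape, Sxx, N),
                                   tp_square(tape, Sx)), 1e-10)
  vy <- pmax(N * Syy - Sy^2, 1e-10)
  den <- tp_sqrt(tape, tp_mul(tape, vx, vy))
  tp_mean(tape, tp_div(tape, num, den))
}

# supervision loss node from a predicted parameter-matrix node (T x 18)
tp_supervision <- function(tape, pred_mat, ref_f0, ref_formants, beta) {
  d0 <- tp_sub(tape, tp_cols(tape, pred_mat, 1L), matrix(ref_f0, ncol = 1L))
  out <- tp_sum(tape, tp_square(tape, d0))
  for (i in 1:4) {
    di <- tp_sub(tape, tp_cols(tape, pred_mat, 1L + i),
                 ref_formants[, i, drop = FALSE])
    out <- tp_add(tape, out, tp_scale(tape, tp_sum(tape, tp_square(tape, di)), beta[i]))
  }
  out
}

# reference loss node: weighted columnwise squared error
tp_reference <- function(tape, pred_mat, ref_mat, weights) {
  d <- tp_square(tape, tp_sub(tape, pred_mat, ref_mat))
  cs <- tp_colsums(tape, d)
  tp_sum(tape, tp_mul(tape, cs, as.numeric(weights)))
}
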