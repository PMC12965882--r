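# Pluggable pitch/formant estimator supplying supervision series when no
# ground-truth parameters accompany a spectrogram or waveform.
#
# Waveform route: frame-wise autocorrelation pitch plus LPC-root formants.
# Spectrogram route: harmonic-comb pitch scoring and spectral-envelope
# peak picking.  Both are deliberately simple references, not a substitute
# for a dedicated phonetics tool.

#' Estimate pitch and formant tracks
#'
#' @param wave Optional waveform (16 kHz); takes precedence when given.
#' @param spec Optional `nv_spectrogram` used when no waveform is given.
#' @param n_formants Formants to return (default 4, the supervised ones).
#' @param f0_range Pitch search range, Hz.
#' @return List with `f0` (per frame, Hz; 0 where unvoiced/silent) and
#'   `formants` (frames x `n_formants`, Hz).
#' @export
estimate_pitch_formants <- function(wave = NULL, spec = NULL,
                                    n_formants = 4L,
                                    f0_range = c(70, 400)) {
  if (is.null(wave) && is.null(spec))
    stop("estimate_pitch_formants: supply wave or spec")
  if (!is.null(wave)) {
    estimate_from_wave(wave, n_formants, f0_range)
  } else {
    estimate_from_spec(unclass(as.matrix(spec)), n_formants, f0_range)
  }
}

estimate_from_wave <- function(wave, n_formants, f0_range) {
  fs <- NV_FS_AUDIO
  hop <- NV_HOP
  win <- 512L
  T <- length(wave) %/% hop
  f0 <- numeric(T)
  fmt <- matrix(0, T, n_formants)
  lag_rng <- rev(round(fs / f0_range))
  wpad <- c(wave, numeric(win))
  for (t in seq_len(T)) {
    seg <- wpad[((t - 1L) * hop + 1L):((t - 1L) * hop + win)]
    seg <- seg - mean(seg)
    if (stats::sd(seg) < 1e-6) next
    ac <- stats::acf(seg, lag.max = lag_rng[2L], plot = FALSE,
                     demean = FALSE)$acf[, 1L, 1L]
    lr <- lag_rng[1L]:lag_rng[2L]
    best <- lr[which.max(ac[lr + 1L])]
    if (ac[best + 1L] > 0.3) f0[t] <- fs / best
    # LPC via Yule-Walker on a pre-emphasized segment; roots give formants
    pe <- seg - c(0, 0.97 * seg[-length(seg)])
    a <- tryCatch(stats::ar.yw(pe, order.max = 12L, aic = FALSE)$ar,
                  error = function(e) NULL)
    if (!is.null(a) && length(a)) {
      r <- polyroot(c(1, -a))
      fr <- Arg(r) * fs / (2 * pi)
      bwr <- -log(pmin(Mod(r), 0.9999)) * fs / pi
      cand <- sort(fr[fr > 90 & fr < 7500 & bwr < 600])
      if (length(cand)) fmt[t, seq_len(min(n_formants, length(cand)))] <-
          cand[seq_len(min(n_formants, length(cand)))]
    }
  }
  list(f0 = f0, formants = fmt)
}

estimate_from_spec <- function(S, n_formants, f0_range) {
  K <- ncol(S)
  freqs <- spec_freqs(K)
  df <- NV_FMAX / K
  T <- nrow(S)
  f0 <- numeric(T)
  fmt <- matrix(0, T, n_formants)
  cand_f0 <- seq(f0_range[1L], f0_range[2L], by = 2)
  for (t in seq_len(T)) {
    row <- S[t, ]
    if (max(row) < 1e-6) next
    score <- vapply(cand_f0, function(f) {
      ks <- round(seq_len(min(8L, floor(NV_FMAX / f))) * f / df) + 1L
      mean(row[pmin(ks, K)])
    }, 1)
    f0[t] <- cand_f0[which.max(score)]
    env <- smooth_ma(log1p(row), 4L)
    pk <- which(diff(sign(diff(env))) < 0) + 1L
    pk <- pk[freqs[pk] > 150]
    if (length(pk)) {
      sel <- pk[order(freqs[pk])][seq_len(min(n_formants, length(pk)))]
      fmt[t, seq_along(sel)] <- freqs[sel]
    }
  }
  list(f0 = f0, formants = fmt)
}
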