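# Magnitude spectrogram container and short-time transforms.
#
# Spectrograms are frames x K nonnegative magnitude matrices at 125
# frames/s spanning [0, 8000] Hz.  The analysis transform uses a Hann
# window of 2K samples with a hop of 128 samples (16 kHz / 125 frames/s),
# so the K retained bins sit at (k-1) * 8000 / K Hz.

NV_FS_AUDIO <- 16000L
NV_HOP <- NV_FS_AUDIO %/% NV_FRAME_RATE  # 128 samples

#' Construct a spectrogram object
#' @param values Frames x K matrix of nonnegative magnitudes.
#' @param frame_rate Frames per second (default 125).
#' @param f_max Upper frequency edge, Hz (default 8000).
#' @return Object of class `nv_spectrogram`.
#' @export
nv_spectrogram <- function(values, frame_rate = NV_FRAME_RATE, f_max = NV_FMAX) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("nv_spectrogram: magnitudes must be nonnegative")
  if (!ncol(values) %in% c(256L, 512L))
    stop("nv_spectrogram: K must be 256 or 512")
  structure(values, frame_rate = frame_rate, f_max = f_max,
            class = c("nv_spectrogram", "matrix"))
}

#' @export
print.nv_spectrogram <- function(x, ...) {
  cat(sprintf("nv_spectrogram: %d frames x %d bins, %.0f frames/s, [0, %.0f] Hz\n",
              nrow(x), ncol(x), attr(x, "frame_rate"), attr(x, "f_max")))
  invisible(x)
}

#' Frequency grid (bin centres) of a K-bin spectrogram
#' @param K Number of bins.
#' @param f_max Upper frequency edge, Hz.
#' @export
spec_freqs <- function(K, f_max = NV_FMAX) (seq_len(K) - 1L) * f_max / K

# Hann window of length n
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

# Framing index matrix: frame t covers samples (t-1)*hop + 1 .. +win.
# The signal is zero-padded on the right so that T = len %/% hop frames fit.
stft_index <- function(n_samples, win, hop = NV_HOP) {
  T <- n_samples %/% hop
  outer(seq_len(T) - 1L, seq_len(win), function(t, j) t * hop + j)
}

#' Magnitude STFT at the package's analysis settings
#' @param x Audio samples at 16 kHz.
#' @param K Retained frequency bins (window length is 2K).
#' @return `nv_spectrogram` with `length(x) %/% 128` frames.
#' @export
stft_mag <- function(x, K = 256L) {
  win <- 2L * K
  idx <- stft_index(length(x), win)
  xp <- c(x, numeric(win))
  fr <- matrix(xp[idx], nrow(idx), win)
  w <- hann(win)
  fr <- fr * matrix(w, nrow(fr), win, byrow = TRUE)
  Z <- t(stats::mvfft(t(fr)))[, seq_len(K), drop = FALSE]
  nv_spectrogram(Mod(Z) * (2 / sum(w)))
}

# complex STFT / inverse pair used by Griffin-Lim
stft_cplx <- function(x, K) {
  win <- 2L * K
  idx <- stft_index(length(x), win)
  xp <- c(x, numeric(win))
  fr <- matrix(xp[idx], nrow(idx), win)
  w <- hann(win)
  fr <- fr * matrix(w, nrow(fr), win, byrow = TRUE)
  t(stats::mvfft(t(fr)))  # frames x 2K, full spectrum
}

istft_cplx <- function(Z, n_samples) {
  win <- ncol(Z)
  w <- hann(win)
  fr <- Re(t(stats::mvfft(t(Z), inverse = TRUE))) / win
  fr <- fr * matrix(w, nrow(fr), win, byrow = TRUE)
  x <- numeric(n_samples + win)
  wsum <- numeric(n_samples + win)
  for (t in seq_len(nrow(fr))) {
    s <- (t - 1L) * NV_HOP
    x[(s + 1L):(s + win)] <- x[(s + 1L):(s + win)] + fr[t, ]
    wsum[(s + 1L):(s + win)] <- wsum[(s + 1L):(s + win)] + w^2
  }
  (x / pmax(wsum, 1e-8))[seq_len(n_samples)]
}

#' Invert a magnitude spectrogram to a waveform (Griffin-Lim)
#'
#' Iterative phase estimation: alternate between enforcing the target
#' magnitudes and projecting onto the set of consistent STFTs.  Returns the
#' waveform together with the per-iteration reconstruction error, which is
#' non-increasing.
#' @param spec `nv_spectrogram` (or frames x K magnitude matrix).
#' @param n_iter Iterations (default 30).
#' @param seed Seed for the random initial phase.
#' @return List with `wave` (16 kHz samples) and `errors` (per iteration).
#' @export
spectrogram_to_waveform <- function(spec, n_iter = 30L, seed = 0L) {
  S <- unclass(as.matrix(spec))
  K <- ncol(S)
  win <- 2L * K
  w <- hann(win)
  Sfull <- cbind(S, matrix(0, nrow(S), 1L),
                 S[, K:2, drop = FALSE]) / (2 / sum(w))  # mirror to full spectrum
  n_samples <- nrow(S) * NV_HOP
  phase <- with_seed(seed, matrix(stats::runif(length(Sfull), 0, 2 * pi),
                                  nrow(Sfull), ncol(Sfull)))
  errors <- numeric(n_iter)
  x <- numeric(n_samples)
  for (it in seq_len(n_iter)) {
    Z <- Sfull * exp(1i * phase)
    x <- istft_cplx(Z, n_samples)
    Z2 <- stft_cplx(x, K)
    errors[it] <- sqrt(mean((Mod(Z2) - Sfull)^2))
    phase <- Arg(Z2)
  }
  list(wave = x, errors = errors)
}

#' Triangular Mel filterbank on the package frequency grid
#' @param n_mels Number of Mel bands (default 80).
#' @param K Spectrogram bins.
#' @param f_max Upper frequency, Hz.
#' @return `n_mels` x K matrix of filter weights.
#' @export
mel_filterbank <- function(n_mels = 80L, K = 256L, f_max = NV_FMAX) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel_to_hz(seq(0, hz_to_mel(f_max), length.out = n_mels + 2L))
  f <- spec_freqs(K, f_max)
  fb <- matrix(0, n_mels, K)
  for (j in seq_len(n_mels)) {
    lo <- pts[j]; ce <- pts[j + 1L]; hi <- pts[j + 2L]
    up <- (f - lo) / max(ce - lo, 1e-9)
    dn <- (hi - f) / max(hi - ce, 1e-9)
    fb[j, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Pearson correlation between two spectrograms
#'
#' Computed over all time-frequency cells; the standard evaluation metric
#' for decoded speech.
#' @param S_hat,S Same-shape magnitude matrices.
#' @return Scalar in `[-1, 1]`.
#' @export
spectrogram_pcc <- function(S_hat, S) {
  a <- as.vector(as.matrix(S_hat)); b <- as.vector(as.matrix(S))
  if (length(a) != length(b)) stop("spectrogram_pcc: shape mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("spectrogram_pcc: zero-variance input")
  stats::cor(a, b)
}
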