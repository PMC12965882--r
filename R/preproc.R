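# ECoG preprocessing: raw multichannel voltage recordings to z-scored
# high-gamma envelope tensors on the electrode grid.
#
# Chain: reject listed bad channels -> common average reference (one scalar
# over all valid channels and time) -> 70-150 Hz band-pass (4th-order
# zero-phase Butterworth, forward-backward) -> analytic-signal magnitude
# (Hilbert envelope) -> polyphase resampling to 125 frames/s -> per-
# electrode z-scoring against averaged pre-trial silent baselines.

#' Construct a raw ECoG recording container
#' @param samples Channels x time matrix, microvolts.
#' @param fs Sampling rate, Hz (> 300 so the 150 Hz band edge resolves).
#' @param channel_grid Channels x 2 integer matrix of (row, col) grid
#'   positions, unique per channel.
#' @param bad_channels Integer indices of rejected channels.
#' @return Object of class `raw_ecog`.
#' @export
raw_ecog <- function(samples, fs, channel_grid, bad_channels = integer(0)) {
  samples <- as.matrix(samples)
  channel_grid <- as.matrix(channel_grid)
  if (fs <= 300) stop("raw_ecog: fs must exceed 300 Hz")
  if (nrow(channel_grid) != nrow(samples) || ncol(channel_grid) != 2L)
    stop("raw_ecog: channel_grid must be channels x 2")
  if (anyDuplicated(channel_grid)) stop("raw_ecog: grid coordinates must be unique")
  structure(list(samples = samples, fs = fs, channel_grid = channel_grid,
                 bad_channels = as.integer(bad_channels)),
            class = "raw_ecog")
}

#' @export
print.raw_ecog <- function(x, ...) {
  cat(sprintf("raw_ecog: %d channels x %d samples at %.0f Hz (%d rejected)\n",
              nrow(x$samples), ncol(x$samples), x$fs, length(x$bad_channels)))
  invisible(x)
}

#' Common average reference
#'
#' Subtracts the single scalar mean over all valid channels and all time
#' points from every sample of every valid channel.
#' @param x A `raw_ecog`.
#' @return The referenced `raw_ecog`.
#' @export
common_average_reference <- function(x) {
  good <- setdiff(seq_len(nrow(x$samples)), x$bad_channels)
  if (length(good) == 0L) stop("common_average_reference: no valid channels")
  x$samples[good, ] <- x$samples[good, ] - mean(x$samples[good, ])
  x
}

# FFT analytic signal magnitude
hilbert_envelope <- function(v) {
  n <- length(v)
  F <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(F * h, inverse = TRUE) / n)
}

#' High-gamma envelope tensor from a referenced recording
#'
#' Band-passes each valid channel to `band` (default 70-150 Hz) with a
#' 4th-order zero-phase Butterworth filter, extracts the analytic-signal
#' envelope, resamples it to `out_rate` frames/s and arranges channels on
#' the electrode grid.  Rejected channels are zero-filled and marked
#' invalid in the mask.
#' @param x A `raw_ecog` (fs >= 300 Hz; must resolve the upper band edge).
#' @param band Pass band `c(lo, hi)` in Hz.
#' @param out_rate Output frame rate (default 125).
#' @return An `ecog_tensor`.
#' @export
high_gamma_envelope <- function(x, band = c(70, 150), out_rate = NV_FRAME_RATE) {
  if (x$fs < 2 * band[2L])
    stop("high_gamma_envelope: sampling rate too low for the requested band")
  bf <- signal::butter(4, band / (x$fs / 2), type = "pass")
  n_in <- ncol(x$samples)
  n_out <- floor(n_in * out_rate / x$fs)
  H <- max(x$channel_grid[, 1L]); W <- max(x$channel_grid[, 2L])
  out <- array(0, c(n_out, H, W))
  mask <- matrix(FALSE, H, W)
  good <- setdiff(seq_len(nrow(x$samples)), x$bad_channels)
  for (ch in good) {
    filt <- signal::filtfilt(bf, x$samples[ch, ])
    env <- hilbert_envelope(filt)
    env_ds <- resample_poly(env, out_rate, x$fs)[seq_len(n_out)]
    out[, x$channel_grid[ch, 1L], x$channel_grid[ch, 2L]] <- env_ds
    mask[x$channel_grid[ch, 1L], x$channel_grid[ch, 2L]] <- TRUE
  }
  ecog_tensor(out, frame_rate = out_rate, valid_mask = mask)
}

# rational-rate polyphase resampling (anti-aliased)
resample_poly <- function(v, p, q) {
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  if (p == 1 && q == 1) return(v)
  up <- numeric(length(v) * p)
  up[seq(1L, length(up), by = p)] <- v * p
  fc <- 1 / max(p, q)
  lp <- signal::fir1(8L * max(p, q), fc)
  fl <- stats::filter(c(up, numeric(length(lp))), lp, sides = 2)
  fl[is.na(fl)] <- 0
  as.numeric(fl[seq(1L, length(v) * p, by = q)])
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Z-score an envelope tensor against pre-trial silent baselines
#'
#' Baseline mean and variance per electrode are computed from the
#' concatenation of the supplied silent windows (e.g. 250 ms before each
#' training trial's stimulus) and applied as `(x - mu) / sigma`.
#' @param env An `ecog_tensor`.
#' @param baselines List of T_b x H x W arrays (the silent windows), or a
#'   single such array.
#' @return Z-scored `ecog_tensor`; errors if any electrode's baseline
#'   variance is zero.
#' @export
zscore_to_baseline <- function(env, baselines) {
  if (!is.list(baselines)) baselines <- list(baselines)
  if (length(baselines) == 0L) stop("zscore_to_baseline: no baseline windows")
  d <- dim(env$values)
  ref <- do.call(rbind, lapply(baselines, function(b) {
    b <- as.array(b)
    matrix(b, dim(b)[1L], d[2L] * d[3L])
  }))
  mu <- colMeans(ref)
  sg <- apply(ref, 2L, stats::sd)
  if (any(sg[as.vector(env$valid_mask)] <= 1e-12))
    stop("zscore_to_baseline: zero baseline variance on a valid electrode")
  flat <- ecog_matrix(env)
  z <- sweep(sweep(flat, 2L, mu), 2L, pmax(sg, 1e-12), "/")
  z[, !as.vector(env$valid_mask)] <- 0
  ecog_tensor(array(z, d), frame_rate = env$frame_rate,
              valid_mask = env$valid_mask)
}
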