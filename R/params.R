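# Speech-parameter and speaker-parameter containers.
#
# The synthesizer is driven by 18 per-frame speech parameters: pitch f0, six
# formant centre frequencies f1..f6 with amplitudes a1..a6, a broadband
# unvoiced filter (centre frequency, bandwidth, amplitude), a voicing weight
# alpha in [0, 1], and loudness.  Speaker parameters are time-invariant:
# unimodal prototype filter shapes for the six formant filters and the
# broadband filter, per-formant bandwidth relations, and a background-noise
# spectrum.

NV_FMAX <- 8000          # Nyquist of the 16 kHz speech signal, Hz
NV_FRAME_RATE <- 125     # spectrogram / ECoG frame rate, frames/s
NV_M_PROTO <- 80L        # prototype filter samples per filter
NV_N_FORMANTS <- 6L      # formant filters
NV_N_HARMONICS <- 80L    # harmonics in the voice excitation

#' Construct a set of per-frame speech parameters
#'
#' @param f0 Pitch (fundamental frequency) per frame, Hz; 0 marks unvoiced.
#' @param formant_f T x 6 matrix of formant centre frequencies, Hz.
#' @param formant_a T x 6 matrix of nonnegative formant amplitudes.
#' @param f_bb,b_bb,a_bb Broadband unvoiced filter centre frequency (Hz),
#'   bandwidth (Hz, must exceed 2000) and amplitude per frame.
#' @param alpha Voicing weight per frame, in `[0, 1]`.
#' @param loudness Nonnegative loudness modulation per frame.
#' @return An object of class `speech_params` (18 parameters per frame).
#' @export
speech_params <- function(f0, formant_f, formant_a, f_bb, b_bb, a_bb,
                          alpha, loudness) {
  p <- structure(list(
    f0 = as.numeric(f0),
    formant_f = as.matrix(formant_f),
    formant_a = as.matrix(formant_a),
    f_bb = as.numeric(f_bb), b_bb = as.numeric(b_bb), a_bb = as.numeric(a_bb),
    alpha = as.numeric(alpha), loudness = as.numeric(loudness)
  ), class = "speech_params")
  validate_speech_params(p)
  p
}

#' Validate speech-parameter invariants
#' @param p A `speech_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_speech_params <- function(p) {
  T <- length(p$f0)
  lens <- c(nrow(p$formant_f), nrow(p$formant_a), length(p$f_bb),
            length(p$b_bb), length(p$a_bb), length(p$alpha), length(p$loudness))
  if (any(lens != T)) stop("speech_params: all series must share one frame count")
  if (ncol(p$formant_f) != NV_N_FORMANTS || ncol(p$formant_a) != NV_N_FORMANTS)
    stop("speech_params: expected 6 formants")
  if (any(p$alpha < 0 | p$alpha > 1)) stop("speech_params: alpha must lie in [0, 1]")
  if (any(p$b_bb <= 2000)) stop("speech_params: broadband bandwidth must exceed 2000 Hz")
  freqs <- c(p$f0, p$formant_f, p$f_bb)
  if (any(freqs < 0 | freqs > NV_FMAX)) stop("speech_params: frequencies must lie in [0, 8000] Hz")
  if (any(p$formant_a < 0) || any(p$a_bb < 0) || any(p$loudness < 0))
    stop("speech_params: amplitudes and loudness must be nonnegative")
  invisible(p)
}

#' @export
print.speech_params <- function(x, ...) {
  cat(sprintf("speech_params: %d frames x 18 parameters (%.0f frames/s)\n",
              length(x$f0), NV_FRAME_RATE))
  cat(sprintf("  f0 %.0f-%.0f Hz, voiced fraction %.2f\n",
              min(x$f0[x$f0 > 0], Inf), max(x$f0, -Inf), mean(x$alpha > 0.5)))
  invisible(x)
}

#' Number of frames of a speech-parameter set
#' @param p A `speech_params` object.
#' @export
n_frames <- function(p) length(p$f0)

# canonical ordering of the 18 per-frame parameters
NV_PARAM_NAMES <- c("f0", paste0("f", 1:6), paste0("a", 1:6),
                    "f_bb", "b_bb", "a_bb", "alpha", "loudness")

#' Convert speech parameters to a frames x 18 matrix
#' @param x A `speech_params` object.
#' @param ... Unused.
#' @export
as.matrix.speech_params <- function(x, ...) {
  m <- cbind(x$f0, x$formant_f, x$formant_a, x$f_bb, x$b_bb, x$a_bb,
             x$alpha, x$loudness)
  colnames(m) <- NV_PARAM_NAMES
  m
}

#' Rebuild speech parameters from a frames x 18 matrix
#' @param m Matrix with columns in the canonical order.
#' @param validate Check invariants (default TRUE).
#' @export
speech_params_from_matrix <- function(m, validate = TRUE) {
  p <- structure(list(
    f0 = m[, 1L], formant_f = m[, 2:7, drop = FALSE],
    formant_a = m[, 8:13, drop = FALSE],
    f_bb = m[, 14L], b_bb = m[, 15L], a_bb = m[, 16L],
    alpha = m[, 17L], loudness = m[, 18L]
  ), class = "speech_params")
  if (validate) validate_speech_params(p)
  p
}

# ---- speaker parameters -------------------------------------------------

#' Map an unconstrained sample vector to a unimodal curve with peak 1
#'
#' The constrained curve is min(cumsum(softplus(r)), reverse-cumsum), i.e.
#' strictly increasing up to a peak and strictly decreasing after it, then
#' normalized so the single peak equals 1.
#' @param raw Unconstrained numeric vector (or matrix, columnwise).
#' @keywords internal
unimodal_from_raw <- function(raw) {
  f1 <- function(r) {
    s <- log1p(exp(pmin(r, 30))) + pmax(r - 30, 0)
    g <- pmin(cumsum(s), rev(cumsum(rev(s))))
    g / max(g)
  }
  if (is.matrix(raw)) apply(raw, 2L, f1) else f1(raw)
}

#' Check that a sampled filter shape increases then decreases with peak 1
#' @param g Numeric vector of filter samples.
#' @keywords internal
is_unimodal <- function(g, tol = 1e-9) {
  pk <- which.max(g)
  up <- if (pk > 1) all(diff(g[1:pk]) > -tol) else TRUE
  dn <- if (pk < length(g)) all(diff(g[pk:length(g)]) < tol) else TRUE
  up && dn && abs(max(g) - 1) < 1e-6
}

#' Construct speaker-specific synthesizer parameters
#'
#' @param proto M x 7 matrix of prototype filter samples (columns: formants
#'   1..6 and the broadband filter), each column unimodal with peak 1,
#'   sampled at M uniform frequencies spanning `[0, f_max]`.
#' @param bw_relation 6 x 3 matrix of per-formant bandwidth-relation triples
#'   (threshold frequency f_theta Hz, slope, baseline bandwidth b0 Hz).
#' @param background Nonnegative background-noise spectrum, length K
#'   (256 for the female profile, 512 for the male profile).
#' @param profile `"female"` or `"male"`.
#' @param raw Optional list of the unconstrained trainable arrays the
#'   constrained values were derived from (kept for training).
#' @return An object of class `speaker_params`.
#' @export
speaker_params <- function(proto, bw_relation, background,
                           profile = c("female", "male"), raw = NULL) {
  profile <- match.arg(profile)
  proto <- as.matrix(proto)
  bw_relation <- as.matrix(bw_relation)
  K <- length(background)
  if (nrow(proto) != NV_M_PROTO || ncol(proto) != NV_N_FORMANTS + 1L)
    stop("speaker_params: proto must be 80 x 7")
  for (j in seq_len(ncol(proto)))
    if (!is_unimodal(proto[, j]))
      stop("speaker_params: prototype filter ", j, " violates unimodality")
  if (!all(dim(bw_relation) == c(6L, 3L)))
    stop("speaker_params: bw_relation must be 6 x 3")
  if (any(bw_relation[, 3L] <= 0)) stop("speaker_params: baseline bandwidth b0 must be positive")
  if (K != speaker_K(profile))
    stop("speaker_params: background length must be ", speaker_K(profile),
         " for the ", profile, " profile")
  if (any(background < 0)) stop("speaker_params: background spectrum must be nonnegative")
  colnames(bw_relation) <- c("f_theta", "slope", "b0")
  structure(list(proto = proto, bw_relation = bw_relation,
                 background = as.numeric(background), profile = profile,
                 M = NV_M_PROTO, K = K, raw = raw),
            class = "speaker_params")
}

#' Frequency bins of a voice profile
#' @param profile `"female"` (256 bins) or `"male"` (512 bins).
#' @export
speaker_K <- function(profile = c("female", "male")) {
  profile <- match.arg(profile)
  if (profile == "female") 256L else 512L
}

#' @export
print.speaker_params <- function(x, ...) {
  cat(sprintf("speaker_params (%s profile): %d learnable scalars\n",
              x$profile, count_learnable_params(x$profile)))
  cat(sprintf("  M = %d prototype samples x 7 filters, 6 x 3 bandwidth triples, K = %d background bins\n",
              x$M, x$K))
  invisible(x)
}

#' Count the scalar learnable synthesizer parameters of a voice profile
#'
#' Prototype samples for the six formant filters and the broadband filter,
#' the per-formant bandwidth-relation triples, and the background-noise
#' spectrum bins.
#' @param profile `"female"` or `"male"`.
#' @return Integer count (834 female, 1090 male).
#' @export
count_learnable_params <- function(profile = c("female", "male")) {
  profile <- match.arg(profile)
  raw <- speaker_raw_init(profile, seed = 0L)
  sum(vapply(raw, length, 1L))
}

#' Initialize unconstrained speaker parameter arrays
#' @param profile Voice profile.
#' @param seed Integer seed for the random initialization.
#' @keywords internal
speaker_raw_init <- function(profile = c("female", "male"), seed = 0L) {
  profile <- match.arg(profile)
  K <- speaker_K(profile)
  with_seed(seed, {
    M <- NV_M_PROTO
    proto_raw <- matrix(0, M, NV_N_FORMANTS + 1L)
    for (j in seq_len(ncol(proto_raw))) {
      # smooth random bump: wide for low formants, narrow for high ones
      width <- stats::runif(1, 4, 10)
      centre <- stats::runif(1, 0.25, 0.75) * M
      proto_raw[, j] <- 2 * exp(-((seq_len(M) - centre) / width)^2) - 2 +
        stats::rnorm(M, 0, 0.05)
    }
    bw_raw <- cbind(stats::rnorm(6, 0, 0.1),           # -> f_theta
                    stats::rnorm(6, 0, 0.1),           # -> slope
                    stats::rnorm(6, 0, 0.1))           # -> b0
    bg_raw <- stats::rnorm(K, -5, 0.1)
    list(proto_raw = proto_raw, bw_raw = bw_raw, bg_raw = bg_raw)
  })
}

# map unconstrained raw arrays to constrained speaker values (numeric path)
speaker_from_raw <- function(raw, profile) {
  proto <- unimodal_from_raw(raw$proto_raw)
  bw <- cbind(
    f_theta = 1500 * plogis(raw$bw_raw[, 1L]),
    slope = 0.12 * plogis(raw$bw_raw[, 2L]),
    b0 = 40 + 160 * plogis(raw$bw_raw[, 3L])
  )
  background <- softplus(raw$bg_raw)
  speaker_params(proto, bw, background, profile, raw = raw)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Evaluate a bandwidth-relation triple at a centre frequency
#'
#' The bandwidth equals the baseline `b0` below the threshold frequency and
#' grows linearly with slope `a` above it, so it is continuous in `f_c`.
#' @param f_c Formant centre frequency, Hz (vectorized).
#' @param relation Numeric triple `c(f_theta, slope, b0)`.
#' @return Bandwidth in Hz.
#' @export
bandwidth_from_center <- function(f_c, relation) {
  relation <- as.numeric(relation)
  f_theta <- relation[1L]; a <- relation[2L]; b0 <- relation[3L]
  if (any(f_c < 0)) stop("bandwidth_from_center: f_c must be nonnegative")
  if (b0 <= 0) stop("bandwidth_from_center: baseline bandwidth b0 must be positive")
  bw <- b0 + a * pmax(f_c - f_theta, 0)
  if (any(bw <= 0)) stop("bandwidth_from_center: parameters produce nonpositive bandwidth")
  bw
}

#' Evaluate a prototype filter on a frequency grid
#'
#' Piecewise-linear interpolation of the M prototype samples, which sit at
#' M uniform frequencies spanning `[0, f_max]`; queries outside the range
#' clamp to the endpoint samples.  Also returns the peak frequency and the
#' half-power bandwidth (span where the gain is at least `1/sqrt(2)` of the
#' unit peak), both computed exactly from the piecewise-linear shape.
#' @param proto_samples Length-M unimodal sample vector with peak 1.
#' @param f Frequencies (Hz) at which to evaluate the filter.
#' @param f_max Upper edge of the sampled range, Hz.
#' @return List with `gain` (same shape as `f`), `f_proto`, `b_proto`.
#' @export
prototype_filter_eval <- function(proto_samples, f, f_max = NV_FMAX) {
  g <- as.numeric(proto_samples)
  M <- length(g)
  if (!is_unimodal(g)) stop("prototype_filter_eval: samples are not unimodal with peak 1")
  xs <- seq(0, f_max, length.out = M)
  fc <- pmin(pmax(f, 0), f_max)
  gain <- stats::approx(xs, g, xout = fc, rule = 2)$y
  if (!is.null(dim(f))) dim(gain) <- dim(f)
  pk <- which.max(g)
  thr <- 1 / sqrt(2)
  cross <- function(i0, i1) {
    # linear crossing of thr between samples i0 and i1
    xs[i0] + (thr - g[i0]) / (g[i1] - g[i0]) * (xs[i1] - xs[i0])
  }
  lo <- xs[1L]
  if (g[1L] < thr) {
    i <- max(which(g[1:pk] < thr))
    lo <- cross(i, i + 1L)
  }
  hi <- xs[M]
  if (g[M] < thr) {
    i <- pk - 1L + min(which(g[pk:M] < thr))
    hi <- cross(i - 1L, i)
  }
  list(gain = gain, f_proto = xs[pk], b_proto = hi - lo)
}

#' Evaluate a shifted and scaled formant filter on a frequency grid
#'
#' The filter is the prototype shape re-centred at `f_c`, stretched so its
#' half-power width equals `bw`, and scaled to peak amplitude `amp`.
#' @param proto Length-M prototype sample vector (unimodal, peak 1).
#' @param f_c Centre frequency, Hz.
#' @param bw Half-power bandwidth, Hz (positive).
#' @param amp Peak amplitude.
#' @param f_grid Frequencies at which to evaluate, Hz.
#' @param f_max Upper edge of the prototype's sampled range, Hz.
#' @return Gain vector of `length(f_grid)`.
#' @export
formant_filter_response <- function(proto, f_c, bw, amp, f_grid,
                                    f_max = NV_FMAX) {
  if (bw <= 0) stop("formant_filter_response: bandwidth must be positive")
  pf <- prototype_filter_eval(proto, numeric(0), f_max)
  arg <- (pf$b_proto / bw) * (f_grid - f_c) + pf$f_proto
  amp * prototype_filter_eval(proto, arg, f_max)$gain
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
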