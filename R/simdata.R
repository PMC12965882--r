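# Seeded synthetic-data generator.
#
# Produces word-like speech-parameter trajectories (~500 ms, alternating
# voiced and unvoiced segments), synthesizes their spectrograms, and mixes
# the (z-scored) parameter series into pseudo-ECoG electrodes through a
# known linear-lagged generative mapping with additive Gaussian noise.  The
# known mapping provides ground truth for decoder-recovery and occlusion
# oracles; it makes no attempt at biophysical realism.

#' Specification of one synthetic trial
#' @param duration_s Trial length in seconds (default 0.5, a word-length
#'   utterance).
#' @param n_segments Number of alternating voiced/unvoiced segments.
#' @param voiced_fraction Target fraction of voiced frames.
#' @param profile Speaker voice profile.
#' @param grid Electrode grid dimensions `c(H, W)` (default 8 x 8).
#' @return List of class `synth_trial_spec`.
#' @export
synth_trial_spec <- function(duration_s = 0.5, n_segments = 3L,
                             voiced_fraction = 0.7,
                             profile = c("female", "male"),
                             grid = c(8L, 8L)) {
  profile <- match.arg(profile)
  stopifnot(duration_s > 0, n_segments >= 1)
  structure(list(duration_s = duration_s, n_segments = as.integer(n_segments),
                 voiced_fraction = voiced_fraction, profile = profile,
                 grid = as.integer(grid)),
            class = "synth_trial_spec")
}

# moving-average smoother with edge replication
smooth_ma <- function(x, k = 5L) {
  n <- length(x)
  xp <- c(rep(x[1L], k), x, rep(x[n], k))
  stats::filter(xp, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)[(k + 1L):(k + n)]
}

# default formant frequency ranges used for targets and encoder heads
formant_ranges <- function() {
  rbind(f1 = c(250, 1000), f2 = c(900, 2600), f3 = c(2300, 3500),
        f4 = c(3200, 4500), f5 = c(4400, 6200), f6 = c(5800, 7600))
}

#' Generate a word-like speech-parameter trajectory
#'
#' Smooth pitch contour (bounded random walk), piecewise formant targets
#' with interpolated transitions, alternating voiced (`alpha -> 1`) and
#' unvoiced (`alpha -> 0`, broadband burst) segments, and a loudness
#' envelope with onset/offset ramps.
#' @param spec A [synth_trial_spec()].
#' @param seed Integer seed; the same seed reproduces the trajectory.
#' @return A `speech_params` object.
#' @export
gen_word_params <- function(spec = synth_trial_spec(), seed = 0L) {
  T <- max(30L, round(spec$duration_s * NV_FRAME_RATE))
  f0_rng <- if (spec$profile == "female") c(160, 300) else c(80, 180)
  with_seed(seed, {
    # voiced/unvoiced segment layout; odd segments voiced
    ns <- spec$n_segments
    n_voiced <- ceiling(ns / 2)
    n_unv <- ns - n_voiced
    vlen <- if (n_voiced > 0) spec$voiced_fraction / n_voiced else 0
    ulen <- if (n_unv > 0) (1 - spec$voiced_fraction) / n_unv else 0
    lens <- rep(c(vlen, ulen), length.out = ns)
    lens <- lens * stats::runif(ns, 0.8, 1.25)
    edges <- round(c(0, cumsum(lens) / sum(lens)) * T)
    edges[ns + 1L] <- T
    voiced <- logical(T)
    seg_of <- integer(T)
    for (s in seq_len(ns)) {
      idx <- (edges[s] + 1L):edges[s + 1L]
      voiced[idx] <- (s %% 2L) == 1L
      seg_of[idx] <- s
    }
    # pitch: word-level intonation gesture (rise-fall or fall arc spanning
    # a natural 15-45 Hz) plus a bounded random walk, smoothed
    f0 <- numeric(T)
    f0[1L] <- stats::runif(1, f0_rng[1L] + 30, f0_rng[2L] - 50)
    step <- diff(f0_rng) / 25
    for (t in 2:T) {
      f0[t] <- min(max(f0[t - 1L] + stats::rnorm(1, 0, step), f0_rng[1L]), f0_rng[2L])
    }
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 15, 45)
    centre_t <- stats::runif(1, 0.3, 0.7) * T
    f0 <- f0 + amp * exp(-((seq_len(T) - centre_t) / (0.35 * T))^2)
    f0 <- pmin(pmax(smooth_ma(f0, 4L), f0_rng[1L]), f0_rng[2L])
    # pitch has no acoustic effect while unvoiced; carry the intonation
    # contour through unvoiced gaps by interpolation (as pitch trackers do)
    if (any(voiced) && any(!voiced)) {
      f0[!voiced] <- stats::approx(which(voiced), f0[voiced],
                                   xout = which(!voiced), rule = 2)$y
      f0 <- pmin(pmax(smooth_ma(f0, 3L), f0_rng[1L]), f0_rng[2L])
    }
    # formants: one target per segment, linear transitions, smoothed
    fr <- formant_ranges()
    ff <- matrix(0, T, 6L)
    anchors_t <- (edges[-length(edges)] + edges[-1L] + 1) / 2
    for (i in 1:6) {
      tg <- stats::runif(ns, fr[i, 1L] * 1.05, fr[i, 2L] * 0.95)
      ff[, i] <- stats::approx(anchors_t, tg, xout = seq_len(T), rule = 2)$y
      ff[, i] <- smooth_ma(ff[, i], 4L)
    }
    # amplitudes: tilt down with formant index, jittered per segment
    base_a <- c(1, 0.7, 0.45, 0.3, 0.2, 0.12)
    fa <- matrix(0, T, 6L)
    for (i in 1:6) {
      tg <- base_a[i] * stats::runif(ns, 0.6, 1.3)
      fa[, i] <- pmax(smooth_ma(stats::approx(anchors_t, tg, xout = seq_len(T),
                                              rule = 2)$y, 4L), 0)
    }
    # voicing weight: smooth switch between segments
    alpha <- smooth_ma(as.numeric(voiced), 2L)
    alpha <- pmin(pmax(alpha, 0), 1)
    # broadband unvoiced filter: burst in unvoiced segments
    f_bb <- rep(stats::runif(1, 3000, 5000), T)
    for (s in which(seq_len(ns) %% 2L == 0L)) {
      f_bb[seg_of == s] <- stats::runif(1, 2500, 6000)
    }
    f_bb <- smooth_ma(f_bb, 4L)
    b_bb <- smooth_ma(rep(stats::runif(1, 2600, 4200), T) +
                        stats::rnorm(T, 0, 50), 6L)
    b_bb <- pmin(pmax(b_bb, 2100), 6000)
    a_bb <- smooth_ma(ifelse(voiced, 0.05, stats::runif(1, 0.4, 0.9)), 3L)
    a_bb <- pmax(a_bb, 0)
    # loudness: onset/offset ramps with slow modulation
    ramp <- 6L
    env <- pmin(1, pmin(seq_len(T), T - seq_len(T) + 1L) / ramp)
    loud <- pmax(env * (0.8 + 0.3 * sin(seq_len(T) / T * pi) +
                          smooth_ma(stats::rnorm(T, 0, 0.05), 5L)), 0)
    speech_params(f0 = f0, formant_f = ff, formant_a = fa, f_bb = f_bb,
                  b_bb = b_bb, a_bb = a_bb, alpha = alpha, loudness = loud)
  })
}

#' Generate random speaker parameters
#' @param profile Voice profile.
#' @param seed Integer seed.
#' @return A `speaker_params` object (invariants hold by construction).
#' @export
gen_speaker <- function(profile = c("female", "male"), seed = 0L) {
  profile <- match.arg(profile)
  speaker_from_raw(speaker_raw_init(profile, seed), profile)
}

#' Construct a generative electrode-to-parameter mapping
#'
#' Each electrode's series is a lagged, weighted sum of the z-scored speech
#' parameter series plus Gaussian noise.
#' @param weights (H*W) x 18 mixing matrix (electrodes in column-major grid
#'   order).
#' @param lags Per-electrode nonnegative integer delays, frames.
#' @param noise_sd Additive noise standard deviation.
#' @param grid `c(H, W)`.
#' @return List of class `generative_mapping`.
#' @export
generative_mapping <- function(weights, lags, noise_sd, grid) {
  weights <- as.matrix(weights)
  E <- prod(grid)
  if (nrow(weights) != E || ncol(weights) != 18L)
    stop("generative_mapping: weights must be (H*W) x 18")
  if (length(lags) != E || any(lags < 0))
    stop("generative_mapping: lags must be nonnegative, one per electrode")
  if (all(weights == 0)) stop("generative_mapping: at least one nonzero weight")
  structure(list(weights = weights, lags = as.integer(lags),
                 noise_sd = noise_sd, grid = as.integer(grid)),
            class = "generative_mapping")
}

#' Generate a random sparse generative mapping
#'
#' A small set of informative electrodes receives random weights over a few
#' speech parameters; all other electrodes are pure noise.
#' @param grid `c(H, W)`.
#' @param n_informative Number of informative electrodes.
#' @param noise_sd Additive noise level (the informative signal mixes have
#'   unit-scale weights).
#' @param max_lag Maximum per-electrode delay in frames.
#' @param seed Integer seed.
#' @export
gen_mapping <- function(grid = c(8L, 8L), n_informative = 18L, noise_sd = 0.1,
                        max_lag = 3L, seed = 0L) {
  E <- prod(grid)
  with_seed(seed, {
    W <- matrix(0, E, 18L)
    info <- sample.int(E, n_informative)
    # graded importance so contribution ranks are well defined.  With the
    # default n_informative = 18 each parameter has its own owner
    # electrode, so the full parameter vector is identifiable from the
    # grid; smaller values share electrodes across parameters (a harder,
    # partially identifiable regime).
    scales <- seq(1.5, 0.5, length.out = n_informative)
    owner <- rep(seq_len(min(n_informative, 18L)), length.out = 18L)
    for (p in 1:18) {
      e <- info[owner[p]]
      W[e, p] <- sample(c(-1, 1), 1) * stats::runif(1, 0.7, 1.3) * scales[owner[p]]
    }
    if (n_informative > 18L) {
      for (j in 19:n_informative) {
        W[info[j], sample(18L, 1L)] <- stats::rnorm(1, 0, 0.5) * scales[j]
      }
    }
    for (j in seq_along(info)) {        # light cross-talk
      k <- sample(18L, 2L)
      W[info[j], k] <- W[info[j], k] + stats::rnorm(2L, 0, 0.15) * scales[j]
    }
    lags <- sample(0:max_lag, E, replace = TRUE)
    generative_mapping(W, lags, noise_sd, grid)
  })
}

# population normalization statistics for the 18 parameters: pooled mean
# and sd over a fixed internal reference sample of trajectories, so every
# trial is normalized identically (a decoder can then invert the mixing
# consistently across trials)
param_norm_stats <- function(profile = "female") {
  key <- paste0("norm_", profile)
  if (is.null(.nv_cache[[key]])) {
    ref <- do.call(rbind, lapply(1:40, function(s)
      as.matrix(gen_word_params(synth_trial_spec(profile = profile),
                                seed = 700000L + s))))
    .nv_cache[[key]] <- list(mu = colMeans(ref),
                             sd = pmax(apply(ref, 2L, stats::sd), 1e-6))
  }
  .nv_cache[[key]]
}

#' Mix speech parameters into a pseudo-ECoG tensor
#'
#' Parameter series are normalized with fixed population statistics (so the
#' electrode-to-parameter mapping is identical for every trial), weighted by
#' the mapping and summed; seeded Gaussian noise is added.  Each electrode
#' leads the acoustics by its lag (neural activity precedes the produced
#' speech, as in motor cortex), so the ECoG-to-speech ground truth stays
#' causal: everything a causal decoder needs about frame t has reached the
#' grid by frame t.
#' @param params `speech_params`.
#' @param mapping `generative_mapping`.
#' @param seed Integer seed for the additive noise.
#' @param profile Voice profile of the population statistics.
#' @return An `ecog_tensor` (T x H x W).
#' @export
gen_pseudo_ecog <- function(params, mapping, seed = 0L, profile = "female") {
  pm <- as.matrix(params)
  T <- nrow(pm)
  ns <- param_norm_stats(profile)
  z <- sweep(sweep(pm, 2L, ns$mu), 2L, ns$sd, "/")
  E <- prod(mapping$grid)
  out <- matrix(0, T, E)
  for (e in seq_len(E)) {
    w <- mapping$weights[e, ]
    if (any(w != 0)) {
      lag <- mapping$lags[e]
      idx <- pmin(seq_len(T) + lag, T)     # electrode leads speech by `lag`
      out[, e] <- z[idx, , drop = FALSE] %*% w
    }
  }
  if (mapping$noise_sd > 0) {
    out <- out + with_seed(seed, matrix(stats::rnorm(T * E, 0, mapping$noise_sd), T, E))
  }
  ecog_tensor(array(out, c(T, mapping$grid[1L], mapping$grid[2L])))
}

#' Generate a paired synthetic dataset with a recorded train/test split
#'
#' Trials are word-like: a small vocabulary of trajectory archetypes is
#' sampled, each trial realizes one archetype (with fresh noise excitation
#' and ECoG noise).  The split holds out 1/8 of the trials (the 350/50
#' proportion), either at random or by holding out whole words.
#' @param n_trials Number of trials (>= 2).
#' @param spec [synth_trial_spec()].
#' @param mapping `generative_mapping` (default [gen_mapping()] on the
#'   spec's grid).
#' @param seed Master seed; all per-trial seeds derive from it.
#' @param n_words Vocabulary size (default about `n_trials / 8`).
#' @param split `"random"` or `"word"` (held-out unique words).
#' @return List of class `nv_dataset` with `trials` (each with `params`,
#'   `spec` spectrogram, `ecog`, `word`), `train`, `test` indices, the
#'   `speaker`, `mapping` and a regeneration `manifest`.
#' @export
make_dataset <- function(n_trials, spec = synth_trial_spec(), mapping = NULL,
                         seed = 0L, n_words = NULL,
                         split = c("random", "word")) {
  split <- match.arg(split)
  stopifnot(n_trials >= 2)
  if (is.null(mapping)) mapping <- gen_mapping(spec$grid, seed = seed + 1L)
  if (is.null(n_words)) n_words <- max(2L, round(n_trials / 8))
  speaker <- gen_speaker(spec$profile, seed = seed + 2L)
  plan <- with_seed(seed, {
    list(words = sample.int(n_words, n_trials, replace = TRUE),
         word_seeds = sample.int(2^30, n_words),
         noise_seeds = sample.int(2^30, n_trials),
         ecog_seeds = sample.int(2^30, n_trials),
         split_draw = stats::runif(n_trials))
  })
  trials <- vector("list", n_trials)
  word_params <- lapply(plan$word_seeds, function(ws) gen_word_params(spec, ws))
  for (i in seq_len(n_trials)) {
    p <- word_params[[plan$words[i]]]
    trials[[i]] <- list(
      params = p,
      spec = synthesize(p, speaker, seed = plan$noise_seeds[i]),
      ecog = gen_pseudo_ecog(p, mapping, seed = plan$ecog_seeds[i], profile = spec$profile),
      word = plan$words[i]
    )
  }
  n_test <- max(1L, round(n_trials / 8))
  if (split == "random") {
    test <- order(plan$split_draw)[seq_len(n_test)]
  } else {
    wtest <- order(tabulate(plan$words, n_words))[seq_len(max(1L, round(n_words / 8)))]
    test <- which(plan$words %in% wtest)
    if (length(test) == 0L) test <- order(plan$split_draw)[seq_len(n_test)]
  }
  train <- setdiff(seq_len(n_trials), test)
  manifest <- list(n_trials = n_trials, seed = seed, n_words = n_words,
                   split = split, spec = unclass(spec),
                   frame_rate = NV_FRAME_RATE, profile = spec$profile)
  structure(list(trials = trials, train = train, test = test,
                 speaker = speaker, mapping = mapping, manifest = manifest),
            class = "nv_dataset")
}

#' @export
print.nv_dataset <- function(x, ...) {
  cat(sprintf("nv_dataset: %d trials (%d train / %d test), %d-word vocabulary\n",
              length(x$trials), length(x$train), length(x$test),
              x$manifest$n_words))
  cat(sprintf("  grid %dx%d, %s speaker, split: %s\n",
              x$mapping$grid[1L], x$mapping$grid[2L],
              x$manifest$profile, x$manifest$split))
  invisible(x)
}
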