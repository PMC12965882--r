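# Speech encoder: spectrogram -> 18 speech parameters per frame.
#
# Temporal convolutional layers over a frequency projection of the linear
# log-spectrogram feed a per-frame MLP head; the pitch channel additionally
# uses features from a Mel-scale projection (pitch is easier to read off a
# Mel axis, the other 17 parameters use the linear axis only).  Together
# with the synthesizer this forms the speech-to-speech auto-encoder whose
# training also fits the speaker parameters.

#' Default encoder configuration
#' @param C Channels of the linear-spectrogram stream.
#' @param C_mel Channels of the Mel stream (pitch head).
#' @param n_conv Temporal conv layers (kernel 5).
#' @param n_mels Mel bands of the pitch stream input.
#' @param Dh Hidden width of the prediction head and pitch MLP.
#' @param profile Voice profile (sets K and the pitch range).
#' @export
encoder_config <- function(C = 48L, C_mel = 24L, n_conv = 3L, n_mels = 80L,
                           Dh = 32L, profile = "female") {
  list(C = C, C_mel = C_mel, n_conv = n_conv, n_mels = n_mels, Dh = Dh,
       c0 = 32L, kernel = 5L, profile = profile, K = speaker_K(profile))
}

# Fixed harmonic comb template bank: cosine similarity between each
# spectrum frame and a comb of narrow Gaussian harmonics at candidate
# pitches.  A classical pitch front end that makes the pitch channel an
# easy readout; the candidate grid spans the profile's pitch range.
comb_templates <- function(K, profile, step = 4) {
  key <- paste0("comb_", K, "_", profile, "_", step)
  if (is.null(.nv_cache[[key]])) {
    fr <- nv_freq_ranges(profile)["f0", ]
    cand <- seq(fr[1L], fr[2L], by = step)
    f <- spec_freqs(K)
    tmpl <- vapply(cand, function(f0) {
      h <- outer(f, f0 * seq_len(floor(NV_FMAX / f0)), function(ff, hf)
        exp(-((ff - hf) / 35)^2))
      v <- rowSums(h)
      v / sqrt(sum(v^2))
    }, numeric(K))
    .nv_cache[[key]] <- list(templates = tmpl, cand = cand)
  }
  .nv_cache[[key]]
}

comb_features <- function(S, profile) {
  ct <- comb_templates(ncol(S), profile)
  cf <- S %*% ct$templates
  cf / pmax(sqrt(rowSums(S^2)), 1e-8)
}

# Analytic pitch track from the comb scores: argmax with parabolic
# refinement, then confidence-weighted kernel smoothing so unvoiced or
# weak frames borrow the neighbouring voiced estimates.  Returned on the
# raw (inverse-sigmoid) scale of the pitch channel.
pitch_track_feature <- function(S, profile) {
  ct <- comb_templates(ncol(S), profile)
  cf <- comb_features(S, profile)
  T <- nrow(cf)
  j <- max.col(cf, ties.method = "first")
  conf <- cf[cbind(seq_len(T), j)]
  step <- ct$cand[2L] - ct$cand[1L]
  f0 <- ct$cand[j]
  ok <- j > 1L & j < ncol(cf)
  if (any(ok)) {
    y1 <- cf[cbind(which(ok), j[ok] - 1L)]
    y2 <- conf[ok]
    y3 <- cf[cbind(which(ok), j[ok] + 1L)]
    d <- 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3 - 1e-12)
    f0[ok] <- f0[ok] + step * pmax(pmin(d, 0.5), -0.5)
  }
  # unvoiced noise matches the densest (lowest-pitch) combs with high
  # cosine; the margin over those templates is the usable voicing evidence
  margin <- conf - pmax(cf[, 1L], cf[, 2L])
  thr <- 0.3 * stats::quantile(margin, 0.9)
  good <- which(margin > pmax(thr, 0.01))
  if (length(good) >= 5L) {
    # a running median over the confident frames rejects octave blips
    med <- stats::runmed(f0[good], 5L)
    good <- good[abs(f0[good] - med) < 0.2 * med]
  }
  f0s <- if (length(good) >= 2L) {
    stats::approx(good, f0[good], xout = seq_len(T), rule = 2)$y
  } else f0
  f0s <- as.numeric(smooth_ma(f0s, 2L))
  rg <- nv_freq_ranges(profile)["f0", ]
  stats::qlogis(pmin(pmax((f0s - rg[1L]) / (rg[2L] - rg[1L]), 0.02), 0.98))
}

n_comb <- function(cfg) length(comb_templates(cfg$K, cfg$profile)$cand)

encoder_init <- function(cfg) {
  D_in <- cfg$K + cfg$n_mels + n_comb(cfg) + 1L
  p <- list(win = he_init(cfg$K, cfg$C), bwin = numeric(cfg$C),
            skip_w = he_init(D_in, cfg$c0), skip_b = numeric(cfg$c0),
            wmel = he_init(cfg$n_mels, cfg$C_mel), bmel = numeric(cfg$C_mel),
            mconv = he_init(cfg$kernel * cfg$C_mel, cfg$C_mel),
            mconv_b = numeric(cfg$C_mel),
            wp1 = he_init(cfg$C + cfg$C_mel + n_comb(cfg), cfg$Dh),
            bp1 = numeric(cfg$Dh),
            wp2 = he_init(cfg$Dh, 1L) * 0.1, bp2 = numeric(1L),
            wpl = he_init(n_comb(cfg), 1L) * 0.1)
  for (l in seq_len(cfg$n_conv)) {
    p[[paste0("conv", l)]] <- he_init(cfg$kernel * cfg$C, cfg$C)
    p[[paste0("conv", l, "_b")]] <- numeric(cfg$C)
  }
  c(p, list(head = head_init(cfg$C + cfg$c0, cfg$Dh, cfg$profile)))
}

# per-frame feature set: log linear spectrum, log Mel spectrum, comb
# scores, and the analytic pitch track (last column, raw scale)
encoder_features <- function(spec_stack, cfg) {
  cbind(log1p(spec_stack),
        log1p(spec_stack %*% t(mel_filterbank(cfg$n_mels, cfg$K))),
        comb_features(spec_stack, cfg$profile),
        pitch_track_feature(spec_stack, cfg$profile))
}

# forward: spec_stack (B*T) x K numeric -> list(pred node, pn list)
encoder_forward <- function(tape, nodes, cfg, spec_stack, B, T) {
  X <- log1p(spec_stack)
  Xm <- log1p(spec_stack %*% t(mel_filterbank(cfg$n_mels, cfg$K)))
  feat <- tp_relu(tape, tp_add_bias(tape, tp_matmul(tape, tp_const(tape, X),
                                                    nodes$win), nodes$bwin))
  for (l in seq_len(cfg$n_conv)) {
    h <- tp_conv1d(tape, feat, nodes[[paste0("conv", l)]],
                   nodes[[paste0("conv", l, "_b")]], B, T, cfg$kernel,
                   causal = FALSE)
    feat <- tp_relu(tape, if (l > 1L) tp_add(tape, h, feat) else h)
  }
  fm <- tp_relu(tape, tp_add_bias(tape, tp_matmul(tape, tp_const(tape, Xm),
                                                  nodes$wmel), nodes$bmel))
  fm <- tp_relu(tape, tp_conv1d(tape, fm, nodes$mconv, nodes$mconv_b,
                                B, T, cfg$kernel, causal = FALSE))
  # linear skip over the full per-frame features (spectrum, Mel, comb);
  # carries the ridge warm start exactly, like the decoder skip path
  Xall <- tp_const(tape, encoder_features(spec_stack, cfg))
  skip <- tp_add_bias(tape, tp_matmul(tape, Xall, nodes$skip_w), nodes$skip_b)
  feat_full <- tp_cbind(tape, list(feat, skip))
  raw <- head_raw(tape, nodes$head, feat_full, B, T, causal = FALSE)
  # pitch channel: additive correction from fused linear + Mel + comb
  cf <- tp_cols(tape, Xall, cfg$K + cfg$n_mels + seq_len(n_comb(cfg)))
  pf <- tp_relu(tape, tp_add_bias(tape, tp_matmul(
    tape, tp_cbind(tape, list(feat, fm, cf)), nodes$wp1), nodes$bp1))
  praw <- tp_add(tape, tp_add_bias(tape, tp_matmul(tape, pf, nodes$wp2), nodes$bp2),
                 tp_matmul(tape, cf, nodes$wpl))
  raw <- tp_cbind(tape, list(tp_add(tape, tp_cols(tape, raw, 1L), praw),
                             tp_cols(tape, raw, 2:18)))
  pred <- head_activations(tape, raw, cfg$profile)
  list(pred = pred, pn = pred_to_pn(tape, pred))
}

#' Encode a spectrogram into speech parameters
#' @param spec `nv_spectrogram` (frames x K).
#' @param model A trained `nv_autoencoder` (or a raw encoder state list
#'   with elements `params` and `config`).
#' @return `speech_params`; carries attribute `trained = FALSE` when the
#'   encoder state is untrained.
#' @export
encode <- function(spec, model) {
  st <- if (inherits(model, "nv_autoencoder"))
    list(params = model$encoder, config = model$config, trained = isTRUE(model$trained))
  else list(params = model$params, config = model$config,
            trained = isTRUE(model$trained))
  S <- unclass(as.matrix(spec))
  T <- nrow(S)
  tape <- nv_tape()
  nodes <- rapply(st$params, function(v) tp_const(tape, v), how = "replace",
                  classes = c("numeric", "matrix", "array"))
  nodes$head$profile <- st$config$profile
  out <- encoder_forward(tape, nodes, st$config, S, 1L, T)
  p <- speech_params_from_matrix(out$pred$value)
  attr(p, "trained") <- isTRUE(st$trained)
  p
}

#' Train the speech-to-speech auto-encoder
#'
#' Jointly fits the encoder network and the learnable speaker parameters by
#' minimizing `L_MSS + lambda1 * L_STOI + lambda2 * L_supervision` over the
#' training trials with Adam (lr 1e-3, beta1 0.9, beta2 0.999).
#' Supervision references (pitch and formants 1-4) come from the dataset's
#' ground-truth parameters when present, otherwise from the pluggable
#' pitch/formant estimator.
#' @param data An `nv_dataset`, or a list of trials each holding `spec` and
#'   optionally `params`.
#' @param config [encoder_config()].
#' @param seed Integer seed; training is deterministic given the seed.
#' @param steps Optimization steps (default 300).
#' @param batch Trials per step (default 8).
#' @param lr Adam learning rate.
#' @param weights Loss weights, see [loss_weights()].
#' @param verbose Print progress every 50 steps.
#' @return An `nv_autoencoder` with the trained encoder, fitted
#'   `speaker_params`, and the training curve.
#' @export
train_autoencoder <- function(data, config = encoder_config(), seed = 0L,
                              steps = 300L, batch = 8L, lr = 1e-3,
                              weights = loss_weights(), verbose = FALSE) {
  trials <- if (inherits(data, "nv_dataset")) data$trials[data$train] else data
  if (length(trials) < 1L) stop("train_autoencoder: need at least one trial")
  K <- config$K
  T <- nrow(trials[[1L]]$spec)
  specs <- lapply(trials, function(tr) unclass(as.matrix(tr$spec)))
  if (!all(vapply(specs, function(S) all(is.finite(S)), TRUE)))
    stop("train_autoencoder: non-finite values in input spectrograms (NaN/Inf)")
  sup <- lapply(trials, function(tr) trial_supervision(tr))
  nc <- param_norm_consts(config$profile)
  band_ind <- octave_band_matrix(K)
  fb_t <- t(mel_filterbank(80L, K))
  with_seed(seed, {
    params <- c(encoder_init(config),
                list(speaker = speaker_raw_init(config$profile,
                                                seed = stats::runif(1) * 2^30)))
    params <- encoder_warmstart(params, config, specs, sup)
    profile <- config$profile
    flat <- params_flatten(params)
    flat <- flat[!vapply(flat, is.character, TRUE)]
    opt <- adam_init(flat, lr = lr)
    curve <- numeric(steps)
    for (step in seq_len(steps)) {
      idx <- sample.int(length(trials), min(batch, length(trials)),
                        replace = length(trials) < batch)
      B <- length(idx)
      S_stack <- do.call(rbind, specs[idx])
      f0_ref <- unlist(lapply(sup[idx], function(s) s$f0))
      fm_ref <- do.call(rbind, lapply(sup[idx], function(s) s$formants))
      noise <- do.call(rbind, lapply(seq_len(B), function(b)
        noise_excitation(T, K, seed = (seed + step * 131L + b) %% 2^30)))
      tape <- nv_tape()
      nodes <- leafify_state(tape, flat)
      enc_nodes <- unflatten_nodes(nodes)
      enc_nodes$head$profile <- profile
      out <- encoder_forward(tape, enc_nodes, config, S_stack, B, T)
      sn <- speaker_nodes_from_raw(tape, enc_nodes$speaker)
      syn <- synth_forward(tape, out$pn, sn, T, K, noise, B = B)
      L <- tp_mss(tape, syn$S, S_stack, fb_t)
      for (b in seq_len(B)) {
        rows <- ((b - 1L) * T + 1L):(b * T)
        st <- tp_stoi(tape, tp_gather_rows(tape, syn$S, rows),
                      S_stack[rows, , drop = FALSE], band_ind)
        L <- tp_add(tape, L, tp_scale(tape, st, -weights$lambda1))
      }
      L <- tp_add(tape, L, tp_scale(
        tape, tp_supervision(tape, out$pred, f0_ref, fm_ref, weights$beta),
        weights$lambda2))
      if (!is.finite(L$value)) stop("train_autoencoder: loss diverged (NaN/Inf) at step ", step)
      tp_backward(tape, L)
      res <- adam_step(opt, flat, collect_grads(nodes))
      flat <- res$params; opt <- res$opt
      curve[step] <- L$value
      if (verbose && step %% 50L == 0L)
        message(sprintf("step %d loss %.2f", step, L$value))
    }
    final <- unflatten_nodes(flat)
    final$head$profile <- profile
    structure(list(encoder = final[setdiff(names(final), "speaker")],
                   speaker = speaker_from_raw(final$speaker, profile),
                   config = config, curve = curve, trained = TRUE,
                   seed = seed),
              class = "nv_autoencoder")
  })
}

# supervision series for one trial: ground truth if present, else estimated
trial_supervision <- function(tr) {
  if (!is.null(tr$params)) {
    m <- as.matrix(tr$params)
    list(f0 = m[, 1L], formants = m[, 2:5, drop = FALSE])
  } else if (!is.null(tr$supervision)) {
    tr$supervision
  } else {
    est <- estimate_pitch_formants(spec = tr$spec)
    list(f0 = est$f0, formants = est$formants[, 1:4, drop = FALSE])
  }
}

# flat named list -> leaf nodes, preserving names
leafify_state <- function(tape, flat) lapply(flat, function(v) tp_leaf(tape, v))

# invert params_flatten's dotted names into a nested list
unflatten_nodes <- function(flat) {
  out <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) out[[parts]] <- flat[[nm]]
    else out[[parts[1L]]][[parts[2L]]] <- flat[[nm]]
  }
  out
}

#' @export
print.nv_autoencoder <- function(x, ...) {
  cat(sprintf("nv_autoencoder (%s profile): %d-channel encoder, %d training steps\n",
              x$config$profile, x$config$C, length(x$curve)))
  cat(sprintf("  final loss %.3f (start %.3f)\n",
              utils::tail(x$curve, 1L), x$curve[1L]))
  invisible(x)
}

#' @export
predict.nv_autoencoder <- function(object, spec, ...) encode(spec, object)

#' Reconstruct a spectrogram through the auto-encoder
#' @param model Trained `nv_autoencoder`.
#' @param spec Input `nv_spectrogram`.
#' @param seed Noise-excitation seed.
#' @return `nv_spectrogram`.
#' @export
reconstruct <- function(model, spec, seed = 0L) {
  p <- encode(spec, model)
  synthesize(p, model$speaker, seed = seed)
}


# Ridge warm start for the encoder: per-frame regression from the full
# feature set onto the raw parameter targets, installed in the linear skip
# path.  Supervision supplies pitch and formants 1-4; the remaining target
# channels start at the training set's mean parameter values.
encoder_warmstart <- function(params, cfg, specs, sup) {
  n_use <- min(length(specs), 80L)
  X <- do.call(rbind, lapply(specs[seq_len(n_use)], function(S)
    encoder_features(S, cfg)))
  tg <- do.call(rbind, lapply(seq_len(n_use), function(i) {
    cbind(sup[[i]]$f0, sup[[i]]$formants)
  }))
  rg <- head_ranges(cfg$profile)
  raw_t <- matrix(0, nrow(tg), 18L)
  for (j in 1:5) {
    u <- pmin(pmax((tg[, j] - rg$lo[j]) / (rg$hi[j] - rg$lo[j]), 0.02), 0.98)
    raw_t[, j] <- stats::qlogis(u)
  }
  xm <- colMeans(X); ym <- colMeans(raw_t)
  Xc <- sweep(X, 2L, xm)
  W <- tryCatch(solve(crossprod(Xc) + diag(ncol(X)),
                      crossprod(Xc, sweep(raw_t, 2L, ym))),
                error = function(e) NULL)
  if (is.null(W)) return(params)
  # the pitch channel starts as the analytic pitch-track feature itself
  W[, 1L] <- 0
  W[ncol(X), 1L] <- 1
  ym[1L] <- 0
  xm[ncol(X)] <- 0
  params$skip_w[, seq_len(18L)] <- W
  params$skip_w[, 19:ncol(params$skip_w)] <- params$skip_w[, 19:ncol(params$skip_w)] * 0.3
  params$skip_b[seq_len(18L)] <- ym - as.numeric(xm %*% W)
  D <- nrow(params$head$wlin)
  c0 <- cfg$c0
  params$head$wlin[] <- 0
  params$head$wlin[D - c0 + seq_len(18L), ] <- diag(18L)
  params$head$w2[] <- 0
  params$head$b2[] <- 0
  params$wp2[] <- 0
  params$wpl[] <- 0
  params
}
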