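# Occlusion-based electrode contribution analysis.
#
# The contribution of electrode i is the mean over test trials of the drop
# in spectrogram PCC when that electrode's (z-scored) input is set to zero:
#   C_i = Mean{ r(S, S_hat) - r(S, S_hat_i) }.
# A noise floor comes from repeating the analysis with a model trained on
# deliberately mismatched (ECoG, speech) pairs (a derangement of the
# trials); contributions below the floor are zeroed in reports.

# decode trial -> synthesized spectrogram, with optional occlusion
decode_spec <- function(decoder, ecog, speaker, occlude = NULL, seed = 0L) {
  x <- ecog
  if (!is.null(occlude)) x$values[, occlude[1L], occlude[2L]] <- 0
  p <- decode(x, decoder)
  synthesize(p, speaker, seed = seed)
}

#' Contribution of one electrode to decoding accuracy
#'
#' @param decoder Trained `nv_decoder`.
#' @param test_set List of trials (each with `ecog` and `spec`).
#' @param electrode `c(row, col)` grid position.
#' @param speaker `speaker_params` for synthesis (default the decoder's).
#' @param seed Noise-excitation seed used for all syntheses.
#' @return Mean PCC drop over the test trials (positive = helpful).
#' @export
electrode_contribution <- function(decoder, test_set, electrode,
                                   speaker = decoder$speaker, seed = 0L) {
  if (length(test_set) == 0L) stop("electrode_contribution: empty test set")
  d <- dim(test_set[[1L]]$ecog$values)
  if (electrode[1L] < 1L || electrode[1L] > d[2L] ||
      electrode[2L] < 1L || electrode[2L] > d[3L])
    stop("electrode_contribution: electrode outside the grid")
  drops <- vapply(test_set, function(tr) {
    S <- unclass(as.matrix(tr$spec))
    r_full <- spectrogram_pcc(decode_spec(decoder, tr$ecog, speaker, NULL, seed), S)
    r_occ <- spectrogram_pcc(decode_spec(decoder, tr$ecog, speaker, electrode, seed), S)
    r_full - r_occ
  }, 1)
  mean(drops)
}

#' Full electrode-contribution map
#'
#' Applies [electrode_contribution()] at every grid position.  Electrodes
#' marked invalid in the tensors' masks receive NA.
#' @inheritParams electrode_contribution
#' @return Object of class `contribution_map`: list with `contrib`
#'   (rows x cols), `n_trials`, and optionally `noise_floor`.
#' @export
contribution_map <- function(decoder, test_set, speaker = decoder$speaker,
                             seed = 0L) {
  if (length(test_set) == 0L) stop("contribution_map: empty test set")
  d <- dim(test_set[[1L]]$ecog$values)
  H <- d[2L]; W <- d[3L]
  mask <- test_set[[1L]]$ecog$valid_mask
  # decode each trial once intact, then once per occluded electrode
  Ss <- lapply(test_set, function(tr) unclass(as.matrix(tr$spec)))
  r_full <- vapply(seq_along(test_set), function(i)
    spectrogram_pcc(decode_spec(decoder, test_set[[i]]$ecog, speaker, NULL, seed),
                    Ss[[i]]), 1)
  contrib <- matrix(NA_real_, H, W)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    if (!mask[h, w]) next
    r_occ <- vapply(seq_along(test_set), function(i)
      spectrogram_pcc(decode_spec(decoder, test_set[[i]]$ecog, speaker,
                                  c(h, w), seed), Ss[[i]]), 1)
    contrib[h, w] <- mean(r_full - r_occ)
  }
  structure(list(contrib = contrib, n_trials = length(test_set),
                 noise_floor = NULL),
            class = "contribution_map")
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(sprintf("contribution_map: %d x %d electrodes over %d trials\n",
              nrow(x$contrib), ncol(x$contrib), x$n_trials))
  top <- order(x$contrib, decreasing = TRUE)[1:3]
  cat(sprintf("  top contributions: %s\n",
              paste(signif(sort(x$contrib, decreasing = TRUE)[1:3], 3),
                    collapse = ", ")))
  if (!is.null(x$noise_floor))
    cat(sprintf("  %d electrodes above the noise floor\n",
                sum(x$contrib > x$noise_floor, na.rm = TRUE)))
  invisible(x)
}

# derangement of 1..n (no fixed point), seeded
derangement <- function(n, seed = 0L) {
  with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) return(p)
    }
  })
}

#' Shuffled-model noise floor for the contribution map
#'
#' Trains a decoder with identical hyperparameters on deliberately
#' mismatched pairs: each trial's ECoG is paired with a different trial's
#' speech (a derangement, so no trial keeps its own speech), then runs the
#' same occlusion analysis.  The resulting map estimates the contribution
#' noise level; `apply_noise_floor()` zeroes contributions below it.
#' @param data `nv_dataset` used for training and evaluation.
#' @param config [decoder_config()] (mirrors the real model's settings).
#' @param seed Seed for the shuffle and the training run.
#' @param ... Passed to [train_decoder()] (steps, batch, lr, ...).
#' @return `contribution_map` from the shuffled model.
#' @export
noise_floor_map <- function(data, config, seed = 0L, ...) {
  trials <- data$trials[data$train]
  if (length(trials) < 2L) stop("noise_floor_map: need at least 2 trials to mismatch")
  perm <- derangement(length(trials), seed)
  shuffled <- lapply(seq_along(trials), function(i) {
    list(ecog = trials[[i]]$ecog, spec = trials[[perm[i]]]$spec,
         params = trials[[perm[i]]]$params)
  })
  dec_sh <- train_decoder(shuffled, config, seed = seed,
                          speaker = data$speaker, ...)
  contribution_map(dec_sh, data$trials[data$test], speaker = data$speaker)
}

#' Zero contributions that do not exceed the noise floor
#' @param cm `contribution_map` of the real model.
#' @param floor_map `contribution_map` from [noise_floor_map()].
#' @return `cm` with sub-floor entries set to 0 and the floor attached.
#' @export
apply_noise_floor <- function(cm, floor_map) {
  cm$noise_floor <- floor_map$contrib
  cm$contrib[!is.na(cm$contrib) & cm$contrib <= floor_map$contrib] <- 0
  cm
}
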