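# Orchestration and evaluation: the two-step training protocol
# (auto-encoder pre-training, then ECoG-decoder training), the evaluation
# metrics (spectrogram PCC, STOI+, per-parameter PCC), YAML configuration,
# and serialization of results.

pcc_safe <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

#' Evaluate a trained decoder on a test set
#'
#' For every test trial, decodes the speech parameters, synthesizes the
#' spectrogram, and reports spectrogram PCC, STOI+, and per-parameter PCCs
#' (voice weight, loudness, pitch, f1, f2) against the references.
#' @param decoder Trained `nv_decoder`.
#' @param test_set List of trials with `ecog`, `spec` and reference
#'   `params`.
#' @param speaker `speaker_params` used for synthesis.
#' @param seed Noise seed for synthesis.
#' @return List of class `nv_report`: `per_trial` data frame and `mean`
#'   summary row.
#' @export
evaluate <- function(decoder, test_set, speaker = decoder$speaker, seed = 0L) {
  if (length(test_set) == 0L) stop("evaluate: empty test set")
  rows <- lapply(seq_along(test_set), function(i) {
    tr <- test_set[[i]]
    ph <- decode(tr$ecog, decoder)
    S_hat <- synthesize(ph, speaker, seed = seed)
    S <- unclass(as.matrix(tr$spec))
    ref <- as.matrix(tr$params)
    pm <- as.matrix(ph)
    data.frame(
      trial = i,
      pcc_spec = spectrogram_pcc(S_hat, S),
      stoi_plus = stoi_plus(unclass(as.matrix(S_hat)), S),
      pcc_alpha = pcc_safe(pm[, "alpha"], ref[, "alpha"]),
      pcc_loudness = pcc_safe(pm[, "loudness"], ref[, "loudness"]),
      pcc_f0 = pcc_safe(pm[, "f0"], ref[, "f0"]),
      pcc_f1 = pcc_safe(pm[, "f1"], ref[, "f1"]),
      pcc_f2 = pcc_safe(pm[, "f2"], ref[, "f2"])
    )
  })
  per_trial <- do.call(rbind, rows)
  means <- colMeans(per_trial[, -1L], na.rm = TRUE)
  structure(list(per_trial = per_trial, mean = means), class = "nv_report")
}

#' @export
print.nv_report <- function(x, ...) {
  cat(sprintf("nv_report over %d trials:\n", nrow(x$per_trial)))
  m <- x$mean
  cat(sprintf("  spectrogram PCC %.3f | STOI+ %.3f\n", m["pcc_spec"], m["stoi_plus"]))
  cat(sprintf("  parameter PCC: alpha %.3f loudness %.3f f0 %.3f f1 %.3f f2 %.3f\n",
              m["pcc_alpha"], m["pcc_loudness"], m["pcc_f0"], m["pcc_f1"], m["pcc_f2"]))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#' @param report `nv_report`.
#' @param dir Output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_trial, file.path(dir, "per_trial.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(report$mean), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default experiment configuration
#'
#' A single nested list covering every stage; can be round-tripped through
#' YAML with [read_config()] / [write_config()].
#' @export
default_config <- function() {
  list(
    data = list(n_trials = 60L, seed = 42L, grid = c(8L, 8L),
                n_informative = 8L, noise_sd = 0.1, split = "random",
                profile = "female"),
    autoencoder = list(C = 32L, C_mel = 16L, n_conv = 2L, Dh = 24L,
                       steps = 300L, batch = 8L, lr = 1e-3),
    decoder = list(backbone = "lstm", causal = TRUE, C = 24L, c0 = 64L,
                   Dh = 32L, steps = 500L, batch = 8L, lr = 3e-3,
                   warmup = 0.7),
    occlusion = list(enabled = TRUE, floor_seed = 1L),
    weights = loss_weights(),
    seed = 0L
  )
}

#' Read / write an experiment configuration as YAML
#' @param path File path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic experiment
#'
#' simulate -> auto-encoder pre-training -> decoder training (guided by the
#' trained encoder) -> evaluation -> optional occlusion analysis.  Fully
#' reproducible from the configuration and its seeds.
#' @param config List from [default_config()] / [read_config()].
#' @param out_dir Optional directory for artifacts (report, config echo).
#' @param verbose Print stage progress.
#' @return List with the dataset, models, evaluation report and (optional)
#'   contribution maps.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           verbose = FALSE) {
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dc <- config$data
  ds <- stage("simulate", make_dataset(
    dc$n_trials, synth_trial_spec(profile = dc$profile, grid = dc$grid),
    mapping = gen_mapping(dc$grid, dc$n_informative, dc$noise_sd,
                          seed = dc$seed + 1L),
    seed = dc$seed, split = dc$split))
  ac <- config$autoencoder
  ae <- stage("train-ae", train_autoencoder(
    ds, encoder_config(C = ac$C, C_mel = ac$C_mel, n_conv = ac$n_conv,
                       Dh = ac$Dh, profile = dc$profile),
    seed = config$seed, steps = ac$steps, batch = ac$batch, lr = ac$lr,
    weights = config$weights))
  dcf <- config$decoder
  dec <- stage("train-dec", train_decoder(
    ds, decoder_config(dcf$backbone, dcf$causal, C = dcf$C, c0 = dcf$c0,
                       Dh = dcf$Dh, profile = dc$profile),
    seed = config$seed + 1L, steps = dcf$steps, batch = dcf$batch,
    lr = dcf$lr, warmup = if (is.null(dcf$warmup)) 0.5 else dcf$warmup,
    speaker = ae$speaker, guidance_model = ae, weights = config$weights))
  report <- stage("evaluate", evaluate(dec, ds$trials[ds$test],
                                       speaker = ae$speaker))
  occ <- NULL
  if (isTRUE(config$occlusion$enabled)) {
    occ <- stage("occlude", {
      cm <- contribution_map(dec, ds$trials[ds$test], speaker = ae$speaker)
      fl <- noise_floor_map(ds, dec$config, seed = config$occlusion$floor_seed,
                            steps = dcf$steps, batch = dcf$batch, lr = dcf$lr)
      apply_noise_floor(cm, fl)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write_report(report, file.path(out_dir, "report"))
    if (!is.null(occ)) {
      utils::write.csv(
        data.frame(row = rep(seq_len(nrow(occ$contrib)), ncol(occ$contrib)),
                   col = rep(seq_len(ncol(occ$contrib)), each = nrow(occ$contrib)),
                   contribution = as.vector(occ$contrib),
                   floor = as.vector(occ$noise_floor)),
        file.path(out_dir, "contributions.csv"), row.names = FALSE)
    }
  }
  list(dataset = ds, autoencoder = ae, decoder = dec, report = report,
       occlusion = occ, config = config)
}
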