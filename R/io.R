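# Plain-text serialization: speech parameters, spectrograms and ECoG
# tensors as CSV matrices with a JSON attribute sidecar (path.json).
# Model checkpoints are saved with saveRDS at run time.

sidecar <- function(path) paste0(path, ".json")

#' Write / read speech parameters as CSV (canonical 18-column layout)
#' @param p `speech_params`.
#' @param path CSV file path.
#' @export
write_speech_params <- function(p, path) {
  utils::write.csv(as.data.frame(as.matrix(p)), path, row.names = FALSE)
  jsonlite::write_json(list(type = "speech_params", frame_rate = NV_FRAME_RATE),
                       sidecar(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_speech_params
#' @export
read_speech_params <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  speech_params_from_matrix(m)
}

#' Write / read a spectrogram as CSV
#' @param spec `nv_spectrogram`.
#' @param path CSV file path.
#' @export
write_spectrogram <- function(spec, path) {
  utils::write.table(unclass(as.matrix(spec)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(type = "spectrogram",
                            frame_rate = attr(spec, "frame_rate"),
                            f_max = attr(spec, "f_max")),
                       sidecar(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spectrogram
#' @export
read_spectrogram <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  meta <- if (file.exists(sidecar(path))) jsonlite::read_json(sidecar(path))
  else list(frame_rate = NV_FRAME_RATE, f_max = NV_FMAX)
  dimnames(m) <- NULL
  nv_spectrogram(m, frame_rate = meta$frame_rate, f_max = meta$f_max)
}

#' Write / read an ECoG tensor as CSV (frames x electrodes, column-major
#' grid order) with grid dimensions in the sidecar
#' @param x `ecog_tensor`.
#' @param path CSV file path.
#' @export
write_ecog <- function(x, path) {
  utils::write.table(ecog_matrix(x), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  d <- dim(x$values)
  jsonlite::write_json(list(type = "ecog", H = d[2L], W = d[3L],
                            frame_rate = x$frame_rate,
                            valid = as.vector(x$valid_mask)),
                       sidecar(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ecog
#' @export
read_ecog <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  meta <- jsonlite::read_json(sidecar(path), simplifyVector = TRUE)
  ecog_tensor(array(m, c(nrow(m), meta$H, meta$W)),
              frame_rate = meta$frame_rate,
              valid_mask = matrix(meta$valid, meta$H, meta$W))
}

#' Export a generated dataset to a directory of plain-text files
#' @param ds `nv_dataset`.
#' @param dir Output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$trials)) {
    tr <- ds$trials[[i]]
    write_speech_params(tr$params, file.path(dir, sprintf("trial%03d_params.csv", i)))
    write_spectrogram(tr$spec, file.path(dir, sprintf("trial%03d_spec.csv", i)))
    write_ecog(tr$ecog, file.path(dir, sprintf("trial%03d_ecog.csv", i)))
  }
  yaml::write_yaml(c(ds$manifest, list(train = ds$train, test = ds$test)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
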