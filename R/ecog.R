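# ECoG tensor container: frames x rows x cols of z-scored high-gamma
# envelopes at 125 frames/s, with a validity mask over the electrode grid.

#' Construct an ECoG tensor
#' @param values T x H x W numeric array (frames x electrode rows x cols).
#' @param frame_rate Frames per second (default 125).
#' @param valid_mask H x W logical matrix of usable electrodes (default all).
#' @return Object of class `ecog_tensor`.
#' @export
ecog_tensor <- function(values, frame_rate = NV_FRAME_RATE, valid_mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("ecog_tensor: values must be T x H x W")
  if (any(!is.finite(values))) stop("ecog_tensor: values must be finite")
  H <- dim(values)[2L]; W <- dim(values)[3L]
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, H, W)
  if (!all(dim(valid_mask) == c(H, W))) stop("ecog_tensor: mask shape mismatch")
  structure(list(values = values, frame_rate = frame_rate,
                 valid_mask = valid_mask), class = "ecog_tensor")
}

#' @export
print.ecog_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ecog_tensor: %d frames x %d x %d electrodes (%d valid), %.0f frames/s\n",
              d[1L], d[2L], d[3L], sum(x$valid_mask), x$frame_rate))
  invisible(x)
}

#' Number of frames of an ECoG tensor
#' @param x An `ecog_tensor`.
#' @export
ecog_frames <- function(x) dim(x$values)[1L]

# flatten to frames x (H*W) matrix, electrodes in column-major grid order
ecog_matrix <- function(x) {
  d <- dim(x$values)
  matrix(x$values, d[1L], d[2L] * d[3L])
}
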