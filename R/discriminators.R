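## Public surfaces of the three adversarial critics.
##
## D1 is a global softmax classifier over the four tumor classes and doubles
## as the downstream classifier used by the evaluation harness.  D2 is a
## patch critic: a spatial grid of realness probabilities, each depending
## only on a ~15-pixel receptive field.  D3 scores the DC-centered
## log-magnitude Fourier spectrum of an image (phase is discarded).

#' Classify an image with the global discriminator D1
#'
#' @param model a [dsclp_model()] (or `dsclp_classifier`).
#' @param x pixel matrix, or a batch (list of samples / H x W x 1 x N array).
#' @return for a single image, a probability vector over the 4 classes
#'   (sums to 1); for a batch, an N x 4 matrix.
#' @export
d1_classify <- function(model, x) {
  b <- as_batch(if (inherits(x, "image_sample")) x$pixels else x)
  cfg <- model$cfg
  assert_that(dim(b)[1] == cfg$image_size && dim(b)[2] == cfg$image_size,
              "image size does not match the model")
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  logits <- d1_forward(tp, P, cfg, t_const(tp, b))$logits$value
  z <- logits - apply(logits, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  if (dim(b)[4] == 1L) as.numeric(p) else p
}

# penultimate 64-d D1 features, used as the pluggable FID extractor
d1_features <- function(model, x) {
  b <- as_batch(x)
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  d1_forward(tp, P, model$cfg, t_const(tp, b), features = TRUE)$features$value
}

#' Score image patches with the local discriminator D2
#'
#' @param model a [dsclp_model()].
#' @param x pixel matrix.
#' @return matrix of patch realness scores in (0, 1); for a model of side S
#'   the grid is (S/4) x (S/4) (16 x 16 at the default 64), each score
#'   covering a 15-pixel receptive field.
#' @export
d2_patch <- function(model, x) {
  b <- as_batch(if (inherits(x, "image_sample")) x$pixels else x)
  assert_that(dim(b)[1] == model$cfg$image_size && dim(b)[2] == model$cfg$image_size,
              "image size does not match the model")
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  m <- d2_forward(tp, P, t_const(tp, b))$value
  if (dim(b)[4] == 1L) batch_to_matrix(m) else m
}

#' Discrete Fourier spectrum of an image
#'
#' Computes the unnormalized 2-D DFT, returning the DC-centered
#' log-compressed magnitude `log(1 + |F|)` together with the raw complex
#' transform (DC at `[1, 1]`, R's `fft` convention).
#'
#' @param x square pixel matrix.
#' @return object of class `spectrum_map` with `$magnitude` (log-compressed,
#'   DC-centered) and `$raw` (complex matrix).
#' @export
spectral_transform <- function(x) {
  x <- as.matrix(x)
  assert_that(all(is.finite(x)), "image must be finite")
  Fm <- fft(x)
  si <- fft_shift_idx(nrow(x)); sj <- fft_shift_idx(ncol(x))
  structure(list(magnitude = log1p(Mod(Fm))[si, sj], raw = Fm),
            class = "spectrum_map")
}

#' Realness score of a spectrum under the Fourier discriminator D3
#'
#' @param model a [dsclp_model()].
#' @param S a `spectrum_map` from [spectral_transform()], or a log-magnitude
#'   matrix of matching size.
#' @return scalar probability in (0, 1).
#' @export
d3_freq <- function(model, S) {
  m <- if (inherits(S, "spectrum_map")) S$magnitude else as.matrix(S)
  assert_that(all(is.finite(m)), "spectrum must be finite")
  assert_that(nrow(m) == model$cfg$image_size && ncol(m) == model$cfg$image_size,
              "spectrum size does not match the model")
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  as.numeric(d3_forward(tp, P, t_const(tp, as_batch(m)))$value)
}
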