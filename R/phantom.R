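## Synthetic brain-MRI phantoms.
##
## Axial T1-weighted contrast-enhanced slices are emulated as an elliptical
## brain region with smooth value-noise texture, a low-frequency bias field,
## additive Gaussian noise, and (for tumor classes) one bright lesion whose
## location, size and texture depend on the class:
##   1 meningioma-analog : medium lesion attached near the brain rim
##   2 glioma-analog     : large diffuse lesion with an irregular boundary
##   3 pituitary-analog  : small lesion at the center
## Class 0 has no lesion.  Images are emitted already standardized to [0,1].

#' Phantom generation settings
#'
#' Describes the geometry and noise model of the synthetic brain phantoms.
#' All downstream components of the package are exercised on images drawn
#' from this model, so the defaults are chosen to make the four classes
#' separable by a simple intensity-histogram classifier while keeping the
#' radiological analogy (rim vs. diffuse vs. central lesion) loose.
#'
#' @param image_size side length in pixels; must be a power of two >= 32.
#' @param brain_axes ellipse semi-axes of the brain region as fractions of
#'   the image side.
#' @param lesion_radius_range named list with per-class `c(min, max)` lesion
#'   radii in pixels for classes `1`, `2`, `3`.
#' @param lesion_center_prior named list with per-class `c(min, max)` radial
#'   position of the lesion center, as a fraction of the brain semi-axes.
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise.
#' @param intensity_bias_amp amplitude of the smooth intensity bias field.
#' @param class_probs length-4 probability vector over classes 0-3 used by
#'   [make_dataset()].
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec()
#' img <- make_phantom(spec, label = 2, seed = 1)
#' range(img$pixels)
phantom_spec <- function(image_size = 64,
                         brain_axes = c(0.42, 0.38),
                         lesion_radius_range = list(`1` = c(4, 7),
                                                    `2` = c(7, 11),
                                                    `3` = c(2.5, 4.5)),
                         lesion_center_prior = list(`1` = c(0.68, 0.88),
                                                    `2` = c(0.05, 0.50),
                                                    `3` = c(0.00, 0.12)),
                         noise_sigma = 0.02,
                         intensity_bias_amp = 0.05,
                         class_probs = rep(0.25, 4)) {
  assert_that(is_pow2(image_size) && image_size >= 32,
              "image_size must be a power of two >= 32")
  assert_that(length(brain_axes) == 2 && all(brain_axes > 0 & brain_axes < 0.5),
              "brain_axes must be two fractions in (0, 0.5)")
  assert_that(length(class_probs) == 4 && all(class_probs >= 0),
              "class_probs must be 4 nonnegative values")
  assert_that(abs(sum(class_probs) - 1) <= 1e-9, "class_probs must sum to 1")
  assert_that(noise_sigma >= 0, "noise_sigma must be nonnegative")
  max_axis_px <- min(brain_axes) * image_size
  for (k in c("1", "2", "3")) {
    r <- lesion_radius_range[[k]]
    assert_that(!is.null(r) && length(r) == 2 && r[1] > 0 && r[2] >= r[1],
                "lesion_radius_range[['", k, "']] must be a positive c(min, max)")
    assert_that(r[2] < max_axis_px,
                "lesion radii must be smaller than the brain semi-axes")
  }
  structure(list(image_size = as.integer(image_size),
                 brain_axes = brain_axes,
                 lesion_radius_range = lesion_radius_range,
                 lesion_center_prior = lesion_center_prior,
                 noise_sigma = noise_sigma,
                 intensity_bias_amp = intensity_bias_amp,
                 class_probs = class_probs),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", x$image_size, "x", x$image_size,
      "| brain axes", paste(x$brain_axes, collapse = "/"),
      "| noise sd", x$noise_sigma, "\n")
  invisible(x)
}

# Smooth "value noise": random values on a coarse lattice, smoothstep-blended
# bilinear upsampling to the full grid.  Cheap stand-in for Perlin noise.
value_noise <- function(H, W, cells = 4) {
  cg <- matrix(rnorm((cells + 1)^2), cells + 1, cells + 1)
  ys <- seq(0, cells, length.out = H)
  xs <- seq(0, cells, length.out = W)
  iy <- pmin(floor(ys), cells - 1); fy <- ys - iy
  ix <- pmin(floor(xs), cells - 1); fx <- xs - ix
  fy <- fy * fy * (3 - 2 * fy)
  fx <- fx * fx * (3 - 2 * fx)
  outer(1 - fy, 1 - fx) * cg[cbind(rep(iy + 1, W), rep(ix + 1, each = H))] +
    outer(fy, 1 - fx) * cg[cbind(rep(iy + 2, W), rep(ix + 1, each = H))] +
    outer(1 - fy, fx) * cg[cbind(rep(iy + 1, W), rep(ix + 2, each = H))] +
    outer(fy, fx) * cg[cbind(rep(iy + 2, W), rep(ix + 2, each = H))]
}

# per-image standardized smooth noise in (-1, 1); standardization keeps the
# intensity histogram of the tissue texture stable across images
value_noise_std <- function(S, cells) {
  v <- value_noise(S, S, cells)
  tanh((v - mean(v)) / stats::sd(v))
}

#' Construct an image sample
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`; square with a
#'   power-of-two side of at least 32.
#' @param label integer class in `0:3` (0 no tumor, 1 meningioma, 2 glioma,
#'   3 pituitary).
#' @param id opaque identifier string.
#' @param meta optional list of generator diagnostics (lesion mask, center).
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(pixels, label, id, meta = NULL) {
  pixels <- as.matrix(pixels)
  check_pixels(pixels)
  assert_that(nrow(pixels) == ncol(pixels) && is_pow2(nrow(pixels)) && nrow(pixels) >= 32,
              "pixels must be square with a power-of-two side >= 32")
  assert_that(length(label) == 1 && label %in% 0:3, "label must be one of 0, 1, 2, 3")
  structure(list(pixels = pixels, label = as.integer(label),
                 id = as.character(id), meta = meta),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("image_sample %s: %dx%d, label %d\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$label))
  invisible(x)
}

#' Generate one synthetic brain phantom
#'
#' Deterministic in `(spec, label, seed)`.  Class 0 contains no lesion;
#' classes 1-3 contain exactly one lesion whose center is drawn from the
#' class prior region and whose mean intensity exceeds the surrounding
#' brain tissue (contrast-enhancement analog).
#'
#' @param spec a [phantom_spec()].
#' @param label class integer in `0:3`.
#' @param seed integer seed.
#' @return an [image_sample()]; `$meta` carries the lesion mask and center.
#' @export
make_phantom <- function(spec, label, seed) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  assert_that(length(label) == 1 && label %in% 0:3, "label must be one of 0, 1, 2, 3")
  S <- spec$image_size
  with_seed(mix_seed(seed, 7919 * (label + 1) + 13), {
    cy <- (S + 1) / 2; cx <- (S + 1) / 2
    a <- spec$brain_axes[1] * S
    b <- spec$brain_axes[2] * S
    yy <- matrix(seq_len(S), S, S)
    xx <- t(yy)
    brain <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
    tex <- value_noise_std(S, 8)
    bias <- spec$intensity_bias_amp * tanh(value_noise(S, S, 2))
    img <- matrix(0.02, S, S)
    img[brain] <- 0.45 + 0.10 * tex[brain] + bias[brain]

    meta <- list(lesion_mask = matrix(FALSE, S, S), lesion_center = NULL)
    if (label > 0) {
      key <- as.character(label)
      rr <- spec$lesion_radius_range[[key]]
      pr <- spec$lesion_center_prior[[key]]
      theta <- runif(1, 0, 2 * pi)
      rfrac <- runif(1, pr[1], pr[2])
      lx <- cx + rfrac * a * cos(theta)
      ly <- cy + rfrac * b * sin(theta)
      radius <- runif(1, rr[1], rr[2])
      sg <- radius / 2
      rho2 <- ((xx - lx)^2 + (yy - ly)^2) / (2 * sg^2)
      # super-Gaussian plateau = enhancing lesion with a sharp margin;
      # amplitudes differ by class so enhancement strength is a class cue
      prof <- switch(key,
        "1" = (0.40 + 0.04 * runif(1)) * exp(-rho2^2),
        "2" = (0.35 + 0.04 * runif(1)) * exp(-rho2^2) *
                (1 + 0.3 * value_noise_std(S, 5)),   # irregular boundary
        "3" = (0.45 + 0.04 * runif(1)) * exp(-rho2^2))
      prof[!brain] <- 0
      img <- img + prof
      meta$lesion_mask <- prof > 0.05
      meta$lesion_center <- c(x = lx, y = ly)
      meta$lesion_radius <- radius
    }
    img <- img + rnorm(S * S, 0, spec$noise_sigma)
    img <- clamp01(img)
    image_sample(img, label, sprintf("ph-%d-%d", as.integer(seed) %% 100000L, label),
                 meta = meta)
  })
}

#' Generate a labelled phantom dataset
#'
#' Labels are drawn i.i.d. from `spec$class_probs`; each sample is rendered
#' from its own seeded substream derived from `(seed, index)`, so per-sample
#' content does not depend on dataset order or size.
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples, >= 1.
#' @param seed integer seed.
#' @return list of [image_sample()] objects with unique ids.
#' @export
make_dataset <- function(spec, n, seed) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  assert_that(length(n) == 1 && n >= 1, "n must be >= 1")
  n <- as.integer(n)
  labels <- with_seed(mix_seed(seed, 0),
                      sample(0:3, n, replace = TRUE, prob = spec$class_probs))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- make_phantom(spec, labels[i], seed = mix_seed(seed, i))
    s$id <- sprintf("ph-%d-%06d", as.integer(seed) %% 100000L, i)
    out[[i]] <- s
  }
  out
}
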