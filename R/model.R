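## Model definition: dual-stream generator (encoder, latent split with
## stream perturbations, contrastive projection head, skip-connected
## dual-path decoder) and the three discriminators.
##
## Architecture (image side S, a power of two >= 32):
##   encoder:  conv 1->8 (s1) | conv 8->16 (s2) | conv 16->32 (s2)
##             | conv 32->32 (s2) | dense -> latent d (default 100)
##             skip activations kept at S (8 ch) and S/2 (16 ch)
##   decoder, global path: dense z_g -> S/8 grid, two upsample+conv stages
##             with skip concatenation, conv to 1 channel
##   decoder, local path:  dense z_l -> S/4 grid, upsample+conv stages,
##             conv to 1 channel (no skips; finer injection scale)
##   image = sigmoid(global_component + local_component)
##   projection head: dense d->64, leaky ReLU, dense 64->32
##   D1: three stride-2 convs, dense -> 64 features -> 4 class logits
##   D2: convs with a 15-pixel receptive field -> (S/4)x(S/4) patch scores
##   D3: two stride-2 convs + dense on the DC-centered log-magnitude DFT

model_config <- function(image_size = 64, latent_dim = 100,
                         d_global = latent_dim %/% 2,
                         d_local = latent_dim - d_global,
                         proj_dim = 32, n_classes = 4) {
  assert_that(is_pow2(image_size) && image_size >= 32,
              "image_size must be a power of two >= 32")
  assert_that(d_global >= 1 && d_local >= 1, "both latent streams need dimension >= 1")
  list(image_size = as.integer(image_size), latent_dim = as.integer(latent_dim),
       d_global = as.integer(d_global), d_local = as.integer(d_local),
       proj_dim = as.integer(proj_dim), n_classes = as.integer(n_classes))
}

init_w <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

# parameter sets ------------------------------------------------------------

generator_params <- function(cfg) {
  S <- cfg$image_size; d <- cfg$latent_dim
  s8 <- S %/% 8L; s4 <- S %/% 4L
  p <- list(
    enc_c1_W = init_w(c(3, 3, 1, 8), 9),    enc_c1_b = numeric(8),
    enc_c2_W = init_w(c(3, 3, 8, 16), 72),  enc_c2_b = numeric(16),
    enc_c3_W = init_w(c(3, 3, 16, 32), 144), enc_c3_b = numeric(32),
    enc_c4_W = init_w(c(3, 3, 32, 32), 288), enc_c4_b = numeric(32),
    enc_fc_W = init_w(c(s8 * s8 * 32, d), s8 * s8 * 32), enc_fc_b = numeric(d),
    prj_fc1_W = init_w(c(d, 64), d),  prj_fc1_b = numeric(64),
    prj_fc2_W = init_w(c(64, cfg$proj_dim), 64), prj_fc2_b = numeric(cfg$proj_dim),
    dg_fc_W = init_w(c(cfg$d_global, s8 * s8 * 32), cfg$d_global), dg_fc_b = numeric(s8 * s8 * 32),
    dg_c1_W = init_w(c(3, 3, 32, 16), 288), dg_c1_b = numeric(16),
    dg_c2_W = init_w(c(3, 3, 32, 8), 288),  dg_c2_b = numeric(8),
    dg_c3_W = init_w(c(3, 3, 16, 8), 144),  dg_c3_b = numeric(8),
    dg_out_W = init_w(c(3, 3, 8, 1), 72),   dg_out_b = numeric(1),
    dl_fc_W = init_w(c(cfg$d_local, s4 * s4 * 8), cfg$d_local), dl_fc_b = numeric(s4 * s4 * 8),
    dl_c1_W = init_w(c(3, 3, 8, 8), 72),    dl_c1_b = numeric(8),
    dl_c2_W = init_w(c(3, 3, 8, 4), 72),    dl_c2_b = numeric(4),
    dl_out_W = init_w(c(3, 3, 4, 1), 36),   dl_out_b = numeric(1)
  )
  p
}

d1_params <- function(cfg) {
  s8 <- cfg$image_size %/% 8L
  list(d1_c1_W = init_w(c(3, 3, 1, 8), 9),    d1_c1_b = numeric(8),
       d1_c2_W = init_w(c(3, 3, 8, 16), 72),  d1_c2_b = numeric(16),
       d1_c3_W = init_w(c(3, 3, 16, 32), 144), d1_c3_b = numeric(32),
       d1_fc1_W = init_w(c(s8 * s8 * 32, 64), s8 * s8 * 32), d1_fc1_b = numeric(64),
       d1_fc2_W = init_w(c(64, cfg$n_classes), 64), d1_fc2_b = numeric(cfg$n_classes))
}

discriminator_params <- function(cfg) {
  s4 <- cfg$image_size %/% 4L
  c(d1_params(cfg),
    list(d2_c1_W = init_w(c(3, 3, 1, 8), 9),    d2_c1_b = numeric(8),
         d2_c2_W = init_w(c(3, 3, 8, 16), 72),  d2_c2_b = numeric(16),
         d2_c3_W = init_w(c(3, 3, 16, 16), 144), d2_c3_b = numeric(16),
         d2_out_W = init_w(c(1, 1, 16, 1), 16), d2_out_b = numeric(1),
         d3_c1_W = init_w(c(3, 3, 1, 8), 9),    d3_c1_b = numeric(8),
         d3_c2_W = init_w(c(3, 3, 8, 16), 72),  d3_c2_b = numeric(16),
         d3_fc_W = init_w(c(s4 * s4 * 16, 1), s4 * s4 * 16), d3_fc_b = numeric(1)))
}

#' Create a dual-stream generator model
#'
#' Initializes all generator and discriminator parameters from a seed.
#'
#' @param image_size square image side; power of two >= 32.
#' @param latent_dim total latent dimension, split into a global and a local
#'   stream (`d_global`/`d_local`, equal halves by default).
#' @param d_global,d_local stream dimensions.
#' @param proj_dim output dimension of the contrastive projection head.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `dsclp_model` holding `$cfg` and `$params`.
#' @export
#' @examples
#' m <- dsclp_model(image_size = 32, seed = 1)
#' x <- make_phantom(phantom_spec(image_size = 32), 2, seed = 5)
#' z <- encode(m, x$pixels)
#' length(z$global_part) + length(z$local_part)
dsclp_model <- function(image_size = 64, latent_dim = 100,
                        d_global = latent_dim %/% 2,
                        d_local = latent_dim - d_global,
                        proj_dim = 32, seed = 1) {
  cfg <- model_config(image_size, latent_dim, d_global, d_local, proj_dim)
  params <- with_seed(mix_seed(seed, 42), c(generator_params(cfg), discriminator_params(cfg)))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "dsclp_model")
}

#' @export
print.dsclp_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("dsclp_model: %dx%d images, latent %d (%d global + %d local), %d parameters\n",
              x$cfg$image_size, x$cfg$image_size, x$cfg$latent_dim,
              x$cfg$d_global, x$cfg$d_local, np))
  invisible(x)
}

g_param_names <- function(params) grep("^(enc|prj|dg|dl)_", names(params), value = TRUE)
d_param_names <- function(params) grep("^(d1|d2|d3)_", names(params), value = TRUE)

param_nodes <- function(tp, params) lapply(params, function(v) t_const(tp, v))

# tape forward passes -------------------------------------------------------

enc_forward <- function(tp, P, cfg, x) {
  s8 <- cfg$image_size %/% 8L
  h1 <- op_lrelu(tp, op_conv(tp, x, P$enc_c1_W, P$enc_c1_b, 1L, 1L))   # S
  h2 <- op_lrelu(tp, op_conv(tp, h1, P$enc_c2_W, P$enc_c2_b, 2L, 1L))  # S/2
  h3 <- op_lrelu(tp, op_conv(tp, h2, P$enc_c3_W, P$enc_c3_b, 2L, 1L))  # S/4
  h4 <- op_lrelu(tp, op_conv(tp, h3, P$enc_c4_W, P$enc_c4_b, 2L, 1L))  # S/8
  z <- op_dense(tp, op_flatten(tp, h4), P$enc_fc_W, P$enc_fc_b)
  list(z = z, skip1 = h1, skip2 = h2)
}

proj_forward <- function(tp, P, z) {
  op_dense(tp, op_lrelu(tp, op_dense(tp, z, P$prj_fc1_W, P$prj_fc1_b)),
           P$prj_fc2_W, P$prj_fc2_b)
}

dec_forward <- function(tp, P, cfg, zg, zl, skip1, skip2) {
  s8 <- cfg$image_size %/% 8L; s4 <- cfg$image_size %/% 4L
  hg <- op_unflatten(tp, op_lrelu(tp, op_dense(tp, zg, P$dg_fc_W, P$dg_fc_b)), s8, s8, 32L)
  hg <- op_lrelu(tp, op_conv(tp, op_upsample2(tp, hg), P$dg_c1_W, P$dg_c1_b, 1L, 1L))  # S/4
  hg <- op_concat_c(tp, op_upsample2(tp, hg), skip2)                                   # S/2
  hg <- op_lrelu(tp, op_conv(tp, hg, P$dg_c2_W, P$dg_c2_b, 1L, 1L))
  hg <- op_concat_c(tp, op_upsample2(tp, hg), skip1)                                   # S
  hg <- op_lrelu(tp, op_conv(tp, hg, P$dg_c3_W, P$dg_c3_b, 1L, 1L))
  gs <- op_conv(tp, hg, P$dg_out_W, P$dg_out_b, 1L, 1L)

  hl <- op_unflatten(tp, op_lrelu(tp, op_dense(tp, zl, P$dl_fc_W, P$dl_fc_b)), s4, s4, 8L)
  hl <- op_lrelu(tp, op_conv(tp, op_upsample2(tp, hl), P$dl_c1_W, P$dl_c1_b, 1L, 1L))  # S/2
  hl <- op_lrelu(tp, op_conv(tp, op_upsample2(tp, hl), P$dl_c2_W, P$dl_c2_b, 1L, 1L))  # S
  gl <- op_conv(tp, hl, P$dl_out_W, P$dl_out_b, 1L, 1L)
  list(gs = gs, gl = gl)
}

# full generator pass: encode, perturb twice, project both views, decode the
# first view.  pert1/pert2 are N x latent_dim noise matrices (already scaled).
g_forward <- function(tp, P, cfg, x, pert1, pert2) {
  enc <- enc_forward(tp, P, cfg, x)
  z1 <- op_add(tp, enc$z, t_const(tp, pert1))
  z2 <- op_add(tp, enc$z, t_const(tp, pert2))
  e1 <- proj_forward(tp, P, z1)
  e2 <- proj_forward(tp, P, z2)
  gcols <- seq_len(cfg$d_global)
  lcols <- cfg$d_global + seq_len(cfg$d_local)
  dec <- dec_forward(tp, P, cfg, op_cols(tp, z1, gcols), op_cols(tp, z1, lcols),
                     enc$skip1, enc$skip2)
  pre <- op_add(tp, dec$gs, dec$gl)
  img <- op_sigmoid(tp, pre)
  list(z = enc$z, z1 = z1, z2 = z2, e1 = e1, e2 = e2,
       gs = dec$gs, gl = dec$gl, pre = pre, img = img,
       skip1 = enc$skip1, skip2 = enc$skip2)
}

d1_forward <- function(tp, P, cfg, x, features = FALSE) {
  h <- op_lrelu(tp, op_conv(tp, x, P$d1_c1_W, P$d1_c1_b, 2L, 1L))
  h <- op_lrelu(tp, op_conv(tp, h, P$d1_c2_W, P$d1_c2_b, 2L, 1L))
  h <- op_lrelu(tp, op_conv(tp, h, P$d1_c3_W, P$d1_c3_b, 2L, 1L))
  f <- op_lrelu(tp, op_dense(tp, op_flatten(tp, h), P$d1_fc1_W, P$d1_fc1_b))
  logits <- op_dense(tp, f, P$d1_fc2_W, P$d1_fc2_b)
  if (features) list(logits = logits, features = f) else list(logits = logits)
}

d2_forward <- function(tp, P, x) {
  h <- op_lrelu(tp, op_conv(tp, x, P$d2_c1_W, P$d2_c1_b, 2L, 1L))
  h <- op_lrelu(tp, op_conv(tp, h, P$d2_c2_W, P$d2_c2_b, 2L, 1L))
  h <- op_lrelu(tp, op_conv(tp, h, P$d2_c3_W, P$d2_c3_b, 1L, 1L))
  op_sigmoid(tp, op_conv(tp, h, P$d2_out_W, P$d2_out_b, 1L, 0L))
}

# D3 consumes the (already computed) spectrum batch, rescaled to keep
# activations of order one.
d3_forward <- function(tp, P, spec_batch) {
  h <- op_scale(tp, spec_batch, 1 / 8)
  h <- op_lrelu(tp, op_conv(tp, h, P$d3_c1_W, P$d3_c1_b, 2L, 1L))
  h <- op_lrelu(tp, op_conv(tp, h, P$d3_c2_W, P$d3_c2_b, 2L, 1L))
  op_sigmoid(tp, op_dense(tp, op_flatten(tp, h), P$d3_fc_W, P$d3_fc_b))
}

## ---- public generator operations -----------------------------------------

#' Latent code constructor
#'
#' @param global_part,local_part numeric vectors for the two streams.
#' @return object of class `latent_code`.
#' @export
latent_code <- function(global_part, local_part) {
  assert_that(all(is.finite(global_part)) && all(is.finite(local_part)),
              "latent entries must be finite")
  assert_that(length(global_part) >= 1 && length(local_part) >= 1,
              "both latent streams need dimension >= 1")
  structure(list(global_part = as.numeric(global_part),
                 local_part = as.numeric(local_part)),
            class = "latent_code")
}

latent_to_vec <- function(z) c(z$global_part, z$local_part)

#' Encode an image into a dual-stream latent code
#'
#' @param model a [dsclp_model()].
#' @param x square pixel matrix in `[0, 1]` matching the model's image size.
#' @param with_skips if `TRUE`, attach the encoder skip activations as
#'   attribute `"skips"` (needed by [decode()]).
#' @return a `latent_code` with `global_part` and `local_part`.
#' @export
encode <- function(model, x, with_skips = FALSE) {
  x <- as.matrix(x)
  check_pixels(x)
  assert_that(nrow(x) == model$cfg$image_size && ncol(x) == model$cfg$image_size,
              "image size does not match the model (expected ",
              model$cfg$image_size, ")")
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  enc <- enc_forward(tp, P, model$cfg, t_const(tp, as_batch(x)))
  zv <- as.numeric(enc$z$value)
  z <- latent_code(zv[seq_len(model$cfg$d_global)],
                   zv[model$cfg$d_global + seq_len(model$cfg$d_local)])
  if (with_skips)
    attr(z, "skips") <- list(skip1 = enc$skip1$value, skip2 = enc$skip2$value)
  z
}

#' Perturb a latent code with stream-specific Gaussian noise
#'
#' @param z a `latent_code`.
#' @param sigma_global,sigma_local nonnegative noise scales for the two
#'   streams.
#' @param seed integer seed; the draw is deterministic in `(z, sigmas, seed)`.
#' @return a perturbed `latent_code`.
#' @export
perturb <- function(z, sigma_global, sigma_local, seed) {
  assert_that(inherits(z, "latent_code"), "z must be a latent_code")
  assert_that(sigma_global >= 0 && sigma_local >= 0, "noise scales must be nonnegative")
  if (sigma_global == 0 && sigma_local == 0) return(z)
  ng <- length(z$global_part); nl <- length(z$local_part)
  with_seed(mix_seed(seed, 211), {
    e <- rnorm(ng + nl)
    latent_code(z$global_part + sigma_global * e[seq_len(ng)],
                z$local_part + sigma_local * e[ng + seq_len(nl)])
  })
}

#' Project a latent code through the contrastive head
#'
#' @param model a [dsclp_model()].
#' @param z a `latent_code` or a numeric vector of length `latent_dim`.
#' @return numeric embedding vector of length `proj_dim`.
#' @export
project <- function(model, z) {
  v <- if (inherits(z, "latent_code")) latent_to_vec(z) else as.numeric(z)
  assert_that(length(v) == model$cfg$latent_dim,
              "latent dimension mismatch (expected ", model$cfg$latent_dim, ")")
  assert_that(all(is.finite(v)), "latent entries must be finite")
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  as.numeric(proj_forward(tp, P, t_const(tp, matrix(v, 1)))$value)
}

#' Decode stream latents into image components
#'
#' @param model a [dsclp_model()].
#' @param z_global,z_local numeric stream latents.
#' @param skips encoder skip activations from the same forward pass (the
#'   `"skips"` attribute of `encode(..., with_skips = TRUE)`).
#' @return list with `global_component`, `local_component` and `image`
#'   (`image = sigmoid(global + local)`, the model's bounded clamp).
#' @export
decode <- function(model, z_global, z_local, skips) {
  cfg <- model$cfg
  assert_that(length(z_global) == cfg$d_global && length(z_local) == cfg$d_local,
              "stream latent dimensions must be ", cfg$d_global, " and ", cfg$d_local)
  assert_that(is.list(skips) && !is.null(skips$skip1) && !is.null(skips$skip2),
              "skips must carry skip1 and skip2 activations")
  S <- cfg$image_size
  assert_that(all(dim(skips$skip1)[1:2] == S) && all(dim(skips$skip2)[1:2] == S / 2),
              "skip activation shapes do not match the model")
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  dec <- dec_forward(tp, P, cfg,
                     t_const(tp, matrix(as.numeric(z_global), 1)),
                     t_const(tp, matrix(as.numeric(z_local), 1)),
                     t_const(tp, skips$skip1), t_const(tp, skips$skip2))
  gs <- batch_to_matrix(dec$gs$value)
  gl <- batch_to_matrix(dec$gl$value)
  list(global_component = gs, local_component = gl, image = logistic(gs + gl))
}

#' Generate an augmented image from an input image
#'
#' Composition encode -> perturb -> decode.  With both noise scales zero this
#' is a plain autoencoder pass and is independent of the seed.
#'
#' @param model a [dsclp_model()].
#' @param x square pixel matrix in `[0, 1]`.
#' @param sigma_global,sigma_local stream noise scales.
#' @param seed integer seed.
#' @return object of class `generator_output` with `image` (in `[0, 1]`),
#'   `global_component`, `local_component` (pre-activation contributions
#'   summing to the pre-clamp output) and `latent` (the perturbed code used).
#' @export
generate <- function(model, x, sigma_global = 0.5, sigma_local = 0.5, seed = 1) {
  x <- as.matrix(x)
  check_pixels(x)
  cfg <- model$cfg
  assert_that(sigma_global >= 0 && sigma_local >= 0, "noise scales must be nonnegative")
  assert_that(nrow(x) == cfg$image_size && ncol(x) == cfg$image_size,
              "image size does not match the model")
  pert <- make_stream_noise(1L, cfg, sigma_global, sigma_local, mix_seed(seed, 211))
  tp <- new_tape()
  P <- param_nodes(tp, model$params)
  fw <- g_forward(tp, P, cfg, t_const(tp, as_batch(x)), pert, pert)
  zv <- as.numeric(fw$z1$value)
  structure(list(image = batch_to_matrix(fw$img$value),
                 global_component = batch_to_matrix(fw$gs$value),
                 local_component = batch_to_matrix(fw$gl$value),
                 latent = latent_code(zv[seq_len(cfg$d_global)],
                                      zv[cfg$d_global + seq_len(cfg$d_local)])),
            class = "generator_output")
}

# N x latent noise matrix with per-stream scales; one deterministic draw
make_stream_noise <- function(N, cfg, sigma_global, sigma_local, seed) {
  if (sigma_global == 0 && sigma_local == 0)
    return(matrix(0, N, cfg$latent_dim))
  with_seed(seed, {
    e <- matrix(rnorm(N * cfg$latent_dim), N, cfg$latent_dim)
    e[, seq_len(cfg$d_global)] <- e[, seq_len(cfg$d_global)] * sigma_global
    e[, cfg$d_global + seq_len(cfg$d_local)] <-
      e[, cfg$d_global + seq_len(cfg$d_local)] * sigma_local
    e
  })
}
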