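## Adversarial training loop.
##
## Each step performs one discriminator update (D1, D2, D3 jointly on the
## weighted aggregate loss) followed by one generator update (adversarial
## terms + CLP + classification-on-generated + L1 reconstruction).  All
## randomness (shuffling, stream noise) is derived from the config seed and
## the step index, so training is bitwise reproducible.

#' Training configuration
#'
#' Two presets are shipped: `"desk"` (batch 16, 5 epochs, learning rate
#' 2e-3) sized for a single CPU, and `"paper"` (batch 64, 50 epochs,
#' learning rate 1e-4) carrying the full-scale protocol.  Adam moments are
#' `beta1 = 0.5`, `beta2 = 0.999` in both.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param image_size,latent_dim model geometry (defaults 64 and 100).
#' @param batch_size at least 2 (the contrastive loss needs an in-batch
#'   negative).
#' @param epochs,learning_rate,adam_beta1,adam_beta2 optimizer settings.
#' @param tau contrastive temperature (> 0).
#' @param weights a [loss_weights()].
#' @param sigma_global,sigma_local stream perturbation scales.
#' @param weight_decay optional decoupled L2 weight decay (0 disables).
#' @param val_frac validation fraction (split fixed by `seed`).
#' @param seed integer seed for all training randomness.
#' @return object of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "paper"), image_size = 64,
                         latent_dim = 100, batch_size = NULL, epochs = NULL,
                         learning_rate = NULL, adam_beta1 = 0.5,
                         adam_beta2 = 0.999, tau = 0.5,
                         weights = loss_weights(), sigma_global = 0.5,
                         sigma_local = 0.5, weight_decay = 0,
                         val_frac = 0.1, seed = 1) {
  preset <- match.arg(preset)
  defaults <- if (preset == "desk") list(batch_size = 16L, epochs = 5L, lr = 2e-3)
              else list(batch_size = 64L, epochs = 50L, lr = 1e-4)
  batch_size <- as.integer(batch_size %||% defaults$batch_size)
  epochs <- as.integer(epochs %||% defaults$epochs)
  learning_rate <- learning_rate %||% defaults$lr
  assert_that(learning_rate >= 0, "learning_rate must be nonnegative")
  assert_that(adam_beta1 >= 0 && adam_beta1 < 1 && adam_beta2 >= 0 && adam_beta2 < 1,
              "Adam betas must lie in [0, 1)")
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(batch_size >= 2, "batch_size must be >= 2 (in-batch negatives)")
  assert_that(tau > 0, "tau must be positive")
  assert_that(inherits(weights, "loss_weights"), "weights must be loss_weights()")
  assert_that(sigma_global >= 0 && sigma_local >= 0, "noise scales must be nonnegative")
  structure(list(preset = preset, image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim), batch_size = batch_size,
                 epochs = epochs, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, tau = tau,
                 weights = weights, sigma_global = sigma_global,
                 sigma_local = sigma_local, weight_decay = weight_decay,
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("train_config [%s]: batch %d, %d epochs, lr %g, tau %g, sigma %g/%g, seed %d\n",
              x$preset, x$batch_size, x$epochs, x$learning_rate, x$tau,
              x$sigma_global, x$sigma_local, x$seed))
  invisible(x)
}

## ---- Adam ----------------------------------------------------------------

# moment buffers mirror the exact shape (and attributes) of each parameter
adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, names_upd, lr, b1, b2, wd = 0, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names_upd) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * params[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

## ---- state ---------------------------------------------------------------

#' Initialize a training state
#'
#' @param config a [train_config()].
#' @return object of class `dsclp_state` holding the model, two Adam states
#'   (generator and discriminators) and the step counter.
#' @export
init_state <- function(config) {
  assert_that(inherits(config, "train_config"), "config must be a train_config")
  model <- dsclp_model(image_size = config$image_size,
                       latent_dim = config$latent_dim, seed = config$seed)
  structure(list(model = model, config = config,
                 opt_g = adam_new(model$params[g_param_names(model$params)]),
                 opt_d = adam_new(model$params[d_param_names(model$params)]),
                 step = 0L, history = NULL),
            class = "dsclp_state")
}

#' @export
print.dsclp_state <- function(x, ...) {
  cat(sprintf("dsclp_state: step %d, %s preset, image %d\n",
              x$step, x$config$preset, x$config$image_size))
  invisible(x)
}

batch_arrays <- function(batch) {
  xb <- as_batch(batch)
  labels <- vapply(batch, function(s) s$label, 0L)
  list(xb = xb, labels = labels)
}

check_finite_losses <- function(comps, step, side) {
  for (nm in names(comps))
    if (!is.finite(comps[[nm]]))
      stop("non-finite loss term '", nm, "' (", side, " side) at step ", step,
           call. = FALSE)
}

# forward the generator and both adversarial heads on one tape; with
# heads = FALSE only the generator pass and CLP are built (enough to obtain
# the fake batch and the CLP value for the discriminator phase)
g_tape <- function(params, cfg, tcfg, xb, labels, pert1, pert2, heads = TRUE) {
  tp <- new_tape()
  P <- param_nodes(tp, params)
  fw <- g_forward(tp, P, cfg, t_const(tp, xb), pert1, pert2)
  e1n <- op_rownorm(tp, fw$e1)
  e2n <- op_rownorm(tp, fw$e2)
  clp <- op_infonce(tp, e1n, e2n, tcfg$tau)
  if (!heads) return(list(tp = tp, P = P, fw = fw, clp = clp))
  logits_fake <- d1_forward(tp, P, cfg, fw$img)$logits
  cls_fake <- op_softmax_ce(tp, logits_fake, labels)
  p2_fake <- d2_forward(tp, P, fw$img)
  adv_g <- op_scale(tp, op_meanlog(tp, p2_fake), -1)
  sp_fake <- op_spectrum(tp, fw$img)
  p3_fake <- d3_forward(tp, P, sp_fake)
  freq_g <- op_scale(tp, op_meanlog(tp, p3_fake), -1)
  recon <- op_mean_abs_diff(tp, fw$img, t_const(tp, xb))
  w <- tcfg$weights
  total <- op_wsum(tp, list(cls_fake, adv_g, freq_g, clp, recon),
                   c(w$lambda_cls, w$lambda_adv, w$lambda_freq, w$lambda_clp,
                     w$lambda_rec))
  list(tp = tp, P = P, fw = fw, clp = clp, cls = cls_fake, adv = adv_g,
       freq = freq_g, recon = recon, total = total,
       p2_fake = p2_fake, p3_fake = p3_fake)
}

#' One adversarial training step
#'
#' Performs one joint discriminator update on the weighted aggregate loss,
#' then one generator update on the adversarial + contrastive +
#' classification-on-generated + reconstruction objective.  Deterministic
#' given the state (which carries the step index) and batch.
#'
#' @param state a `dsclp_state`.
#' @param batch list of >= 2 [image_sample()] objects.
#' @return list with the updated `state` and the two `loss_report`s
#'   (`d_report`, `g_report`).
#' @export
train_step <- function(state, batch) {
  assert_that(inherits(state, "dsclp_state"), "state must come from init_state()/fit()")
  assert_that(length(batch) >= 2, "batch must contain at least 2 samples")
  tcfg <- state$config
  cfg <- state$model$cfg
  step <- state$step + 1L
  ba <- batch_arrays(batch)
  N <- length(batch)
  pert1 <- make_stream_noise(N, cfg, tcfg$sigma_global, tcfg$sigma_local,
                             mix_seed(tcfg$seed, 50000 + 2L * step))
  pert2 <- make_stream_noise(N, cfg, tcfg$sigma_global, tcfg$sigma_local,
                             mix_seed(tcfg$seed, 50001 + 2L * step))
  params <- state$model$params
  w <- tcfg$weights

  ## ---- discriminator update (fake batch held fixed) ----
  gt0 <- g_tape(params, cfg, tcfg, ba$xb, ba$labels, pert1, pert2, heads = FALSE)
  fake <- gt0$fw$img$value
  clp_val <- as.numeric(gt0$clp$value)

  tp <- new_tape()
  P <- param_nodes(tp, params)
  xr <- t_const(tp, ba$xb)
  xf <- t_const(tp, fake)
  cls_real <- op_softmax_ce(tp, d1_forward(tp, P, cfg, xr)$logits, ba$labels)
  p2r <- d2_forward(tp, P, xr); p2f <- d2_forward(tp, P, xf)
  adv_d <- op_wsum(tp, list(op_meanlog(tp, p2r), op_meanlog1m(tp, p2f)), c(-1, -1))
  p3r <- d3_forward(tp, P, op_spectrum(tp, xr))
  p3f <- d3_forward(tp, P, op_spectrum(tp, xf))
  freq_d <- op_wsum(tp, list(op_meanlog(tp, p3r), op_meanlog1m(tp, p3f)), c(-1, -1))
  d_total <- op_wsum(tp, list(cls_real, adv_d, freq_d),
                     c(w$lambda_cls, w$lambda_adv, w$lambda_freq))
  d_comps <- list(clp = clp_val, cls = as.numeric(cls_real$value),
                  adv_patch = as.numeric(adv_d$value),
                  adv_freq = as.numeric(freq_d$value))
  check_finite_losses(d_comps, step, "discriminator")
  tape_backward(tp, d_total)
  d_names <- d_param_names(params)
  d_grads <- lapply(P[d_names], function(nd) nd$grad)
  up <- adam_step(params, d_grads, state$opt_d, d_names, tcfg$learning_rate,
                  tcfg$adam_beta1, tcfg$adam_beta2, tcfg$weight_decay)
  params <- up$params
  state$opt_d <- up$opt
  d_report <- total_loss(d_comps, w, "discriminator", tcfg$tau)

  ## ---- generator update (through the updated discriminators) ----
  ## The generator forward pass of gt0 is still valid (G parameters did not
  ## change during the D update), so the adversarial heads are attached to
  ## the same tape with the freshly updated discriminator parameters.
  gt <- gt0
  Ph <- param_nodes(gt$tp, params[d_names])
  cls_fake <- op_softmax_ce(gt$tp, d1_forward(gt$tp, Ph, cfg, gt$fw$img)$logits,
                            ba$labels)
  adv_g <- op_scale(gt$tp, op_meanlog(gt$tp, d2_forward(gt$tp, Ph, gt$fw$img)), -1)
  p3g <- d3_forward(gt$tp, Ph, op_spectrum(gt$tp, gt$fw$img))
  freq_g <- op_scale(gt$tp, op_meanlog(gt$tp, p3g), -1)
  recon <- op_mean_abs_diff(gt$tp, gt$fw$img, t_const(gt$tp, ba$xb))
  g_total <- op_wsum(gt$tp, list(cls_fake, adv_g, freq_g, gt$clp, recon),
                     c(w$lambda_cls, w$lambda_adv, w$lambda_freq, w$lambda_clp,
                       w$lambda_rec))
  g_comps <- list(clp = as.numeric(gt$clp$value), cls = as.numeric(cls_fake$value),
                  adv_patch = as.numeric(adv_g$value),
                  adv_freq = as.numeric(freq_g$value),
                  recon = as.numeric(recon$value))
  check_finite_losses(g_comps, step, "generator")
  tape_backward(gt$tp, g_total)
  g_names <- g_param_names(params)
  g_grads <- lapply(gt$P[g_names], function(nd) nd$grad)
  up <- adam_step(params, g_grads, state$opt_g, g_names, tcfg$learning_rate,
                  tcfg$adam_beta1, tcfg$adam_beta2, tcfg$weight_decay)
  state$opt_g <- up$opt
  state$model$params <- up$params
  state$step <- step
  g_report <- total_loss(g_comps, w, "generator", tcfg$tau)
  list(state = state, d_report = d_report, g_report = g_report)
}

#' Audit generator gradients
#'
#' Runs one generator-side forward/backward on a batch and reports, per
#' parameter group, the gradient norm and the fraction of exactly-zero
#' entries.
#'
#' @param state a `dsclp_state`.
#' @param batch list of [image_sample()] objects.
#' @return data frame with columns `param`, `n`, `norm`, `frac_zero`.
#' @export
gradient_audit <- function(state, batch) {
  tcfg <- state$config
  cfg <- state$model$cfg
  ba <- batch_arrays(batch)
  N <- length(batch)
  pert1 <- make_stream_noise(N, cfg, tcfg$sigma_global, tcfg$sigma_local,
                             mix_seed(tcfg$seed, 61))
  pert2 <- make_stream_noise(N, cfg, tcfg$sigma_global, tcfg$sigma_local,
                             mix_seed(tcfg$seed, 62))
  gt <- g_tape(state$model$params, cfg, tcfg, ba$xb, ba$labels, pert1, pert2)
  tape_backward(gt$tp, gt$total)
  g_names <- g_param_names(state$model$params)
  rows <- lapply(g_names, function(nm) {
    g <- gt$P[[nm]]$grad
    if (is.null(g)) g <- 0 * state$model$params[[nm]]
    data.frame(param = nm, n = length(g), norm = sqrt(sum(g^2)),
               frac_zero = mean(g == 0))
  })
  do.call(rbind, rows)
}

# mean zero-noise reconstruction quality over a sample list
reconstruction_quality <- function(model, samples) {
  if (!length(samples)) return(c(ssim = NA_real_, psnr = NA_real_))
  vs <- vapply(samples, function(s) {
    out <- generate(model, s$pixels, 0, 0, seed = 1)
    c(ssim(s$pixels, out$image), psnr(s$pixels, out$image))
  }, numeric(2))
  c(ssim = mean(vs[1, ]), psnr = mean(vs[2, ]))
}

#' Train the full adversarial model
#'
#' Splits off a seeded validation fraction, then runs epochs of alternating
#' discriminator/generator updates.  The history records the mean loss terms
#' per epoch plus validation SSIM/PSNR between inputs and their zero-noise
#' reconstructions; row `epoch = 0` is the pre-training baseline.
#'
#' @param dataset nonempty list of [image_sample()] objects.
#' @param config a [train_config()].
#' @param checkpoint_dir optional directory; when given, a checkpoint is
#'   written after every epoch and training can be resumed from it.
#' @param verbose print one line per epoch.
#' @return a `dsclp_state` with `$history` (data frame).
#' @export
fit <- function(dataset, config, checkpoint_dir = NULL, verbose = FALSE) {
  assert_that(length(dataset) >= 2, "dataset must contain at least 2 samples")
  state <- init_state(config)
  n <- length(dataset)
  n_val <- max(1L, floor(config$val_frac * n))
  val_idx <- with_seed(mix_seed(config$seed, 999), sample.int(n, n_val))
  val <- dataset[val_idx]
  tr <- dataset[-val_idx]
  assert_that(length(tr) >= config$batch_size, "too few training samples for one batch")

  rq <- reconstruction_quality(state$model, val)
  hist <- data.frame(epoch = 0L, d_total = NA_real_, g_total = NA_real_,
                     clp = NA_real_, cls = NA_real_, adv_patch = NA_real_,
                     adv_freq = NA_real_, recon = NA_real_,
                     val_ssim = rq["ssim"], val_psnr = rq["psnr"],
                     row.names = NULL)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(mix_seed(config$seed, 8000 + ep), sample.int(length(tr)))
    nb <- length(tr) %/% config$batch_size
    acc <- numeric(8)
    for (bi in seq_len(nb)) {
      idx <- ord[(bi - 1L) * config$batch_size + seq_len(config$batch_size)]
      res <- train_step(state, tr[idx])
      state <- res$state
      acc <- acc + c(res$d_report$total_discriminator, res$g_report$total_generator,
                     res$g_report$clp, res$g_report$cls, res$g_report$adv_patch,
                     res$g_report$adv_freq, res$g_report$recon, 1)
    }
    rq <- reconstruction_quality(state$model, val)
    hist <- rbind(hist, data.frame(epoch = ep, d_total = acc[1] / acc[8],
                                   g_total = acc[2] / acc[8], clp = acc[3] / acc[8],
                                   cls = acc[4] / acc[8], adv_patch = acc[5] / acc[8],
                                   adv_freq = acc[6] / acc[8], recon = acc[7] / acc[8],
                                   val_ssim = rq["ssim"], val_psnr = rq["psnr"],
                                   row.names = NULL))
    if (verbose)
      message(sprintf("epoch %d: G %.3f D %.3f val SSIM %.4f", ep,
                      acc[2] / acc[8], acc[1] / acc[8], rq["ssim"]))
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      state$history <- hist
      save_checkpoint(state, file.path(checkpoint_dir,
                                       sprintf("epoch-%03d.rds", ep)))
    }
  }
  state$history <- hist
  state
}

#' Append generated variants to a dataset
#'
#' For each input image, `level` seeded variants are generated and appended
#' with the source label inherited; the result has `n * (1 + level)` samples.
#'
#' @param dataset list of [image_sample()] objects.
#' @param state a `dsclp_state` (trained or freshly initialized).
#' @param level nonnegative integer number of variants per input.
#' @param seed integer seed.
#' @return augmented list of samples.
#' @export
augment_dataset <- function(dataset, state, level, seed = 1) {
  assert_that(length(level) == 1 && level >= 0, "level must be a nonnegative integer")
  if (level == 0) return(dataset)
  vars <- make_variants(dataset, state, as.integer(level), seed,
                        state$config$sigma_global, state$config$sigma_local)
  c(dataset, vars)
}

## ---- checkpoints ---------------------------------------------------------

CHECKPOINT_FORMAT <- "dsclpgan-checkpoint/1"

#' Save / load a training checkpoint
#'
#' The archive embeds a format-version string and the full config snapshot;
#' [load_checkpoint()] refuses archives with a different format version.
#'
#' @param state a `dsclp_state`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `dsclp_state`.
#' @export
save_checkpoint <- function(state, path) {
  assert_that(inherits(state, "dsclp_state"), "state must be a dsclp_state")
  saveRDS(list(format = CHECKPOINT_FORMAT, package_version = "0.1.0",
               state = unclass(state)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), "checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, CHECKPOINT_FORMAT))
    stop_input("checkpoint format '", obj$format %||% "<missing>",
               "' does not match expected '", CHECKPOINT_FORMAT, "'")
  structure(obj$state, class = "dsclp_state")
}

## ---- small classifier (frozen D1 architecture) ---------------------------

#' Train a stand-alone tumor classifier (D1 clone)
#'
#' Trains the D1 architecture with plain cross-entropy for a fixed number of
#' gradient steps, drawing each mini-batch i.i.d. (seeded) from the sample
#' pool.  The fixed step budget makes runs over differently-sized training
#' pools compute-comparable: duplicating samples only reweights the batch
#' distribution, so accuracy differences between augmentation levels reflect
#' data diversity rather than extra optimizer steps.  This is the classifier
#' used by [diversity_eval()] and the default FID feature extractor.
#'
#' @param samples list of [image_sample()] objects.
#' @param image_size image side (defaults to the samples' size).
#' @param steps number of gradient steps.
#' @param batch_size,lr mini-batch size and Adam learning rate.
#' @param seed integer seed (init, batch sampling).
#' @return object of class `dsclp_classifier`.
#' @export
train_classifier <- function(samples, image_size = nrow(samples[[1]]$pixels),
                             steps = 300, batch_size = 16, lr = 2e-3, seed = 1) {
  assert_that(length(samples) >= 2, "need at least 2 samples")
  cfg <- model_config(image_size = image_size)
  params <- with_seed(mix_seed(seed, 17), d1_params(cfg))
  opt <- adam_new(params)
  nms <- names(params)
  n <- length(samples)
  for (stp in seq_len(steps)) {
    idx <- with_seed(mix_seed(seed, 2000 + stp), sample.int(n, min(batch_size, n)))
    ba <- batch_arrays(samples[idx])
    tp <- new_tape()
    P <- param_nodes(tp, params)
    ce <- op_softmax_ce(tp, d1_forward(tp, P, cfg, t_const(tp, ba$xb))$logits,
                        ba$labels)
    tape_backward(tp, ce)
    grads <- lapply(P[nms], function(nd) nd$grad)
    up <- adam_step(params, grads, opt, nms, lr, 0.9, 0.999)
    params <- up$params
    opt <- up$opt
  }
  structure(list(cfg = cfg, params = params), class = "dsclp_classifier")
}

#' Classifier accuracy on a sample list
#'
#' @param clf a `dsclp_classifier` (or any object accepted by
#'   [d1_classify()]).
#' @param samples list of [image_sample()] objects.
#' @return fraction of correct argmax predictions.
#' @export
classifier_accuracy <- function(clf, samples) {
  p <- d1_classify(clf, samples)
  if (!is.matrix(p)) p <- matrix(p, 1)
  pred <- max.col(p, ties.method = "first") - 1L
  truth <- vapply(samples, function(s) s$label, 0L)
  mean(pred == truth)
}
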