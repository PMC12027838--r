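## Scalar training objectives.
##
## The contrastive latent projection (CLP) loss is a temperature-scaled
## InfoNCE over cosine similarities: for an anchor embedding z1, a positive
## z2 (a second perturbed view of the same image) and in-batch negatives zj,
##
##   L = -log[ exp(cos(z1, z2)/tau) /
##             (exp(cos(z1, z2)/tau) + sum_j exp(cos(z1, zj)/tau)) ]
##
## The denominator contains the positive term plus all negative terms.
## Adversarial terms follow the standard non-saturating GAN convention:
## the discriminator side minimizes -E[log D(real)] - E[log(1 - D(fake))]
## and the generator side minimizes -E[log D(fake)].  A probability floor
## of 1e-12 is applied inside every logarithm.

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  assert_that(na > 0 && nb > 0, "zero-norm embedding in cosine similarity")
  sum(a * b) / (na * nb)
}

#' Contrastive latent projection (InfoNCE) loss
#'
#' @param anchor,positive numeric embedding vectors (nonzero norm).
#' @param negatives list of >= 1 embedding vectors (nonzero norm).
#' @param tau positive temperature; smaller values penalize similarity
#'   differences more sharply.
#' @return nonnegative scalar loss.  Invariant to rescaling any embedding by
#'   a positive constant (only cosine similarities enter).
#' @export
#' @examples
#' a <- c(1, 0); p <- c(1, 0); n <- list(c(0, 1))
#' clp_loss(a, p, n, tau = 1)  # log(1 + exp(-1))
clp_loss <- function(anchor, positive, negatives, tau) {
  assert_that(length(tau) == 1 && is.finite(tau) && tau > 0, "tau must be positive")
  assert_that(is.list(negatives) && length(negatives) >= 1,
              "at least one negative embedding is required")
  s_pos <- cosine_sim(anchor, positive)
  s_neg <- vapply(negatives, function(z) cosine_sim(anchor, z), 0)
  l <- c(s_pos, s_neg) / tau
  m <- max(l)
  -(l[1] - m - log(sum(exp(l - m))))
}

#' Classification cross-entropy of D1
#'
#' Cross-entropy of predicted class probabilities against a one-hot ground
#' truth.  Given a probability matrix and a label vector, the mean over
#' samples is returned.
#'
#' @param probs probability vector over classes (or an N x c matrix).
#' @param label integer class in `0:(c-1)` (or a length-N vector).
#' @return nonnegative scalar.
#' @export
classification_loss <- function(probs, label) {
  p <- if (is.matrix(probs)) probs else matrix(probs, 1)
  label <- as.integer(label)
  assert_that(all(label >= 0 & label < ncol(p)), "label out of range")
  assert_that(length(label) == nrow(p), "one label per probability row is required")
  assert_that(all(p >= 0) && all(abs(rowSums(p) - 1) < 1e-6),
              "probs must be a probability simplex vector")
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), label + 1L)], EPS_LOG)))
}

adv_side <- function(side) match.arg(side, c("discriminator", "generator"))

#' Patch adversarial loss of D2
#'
#' @param real_maps,fake_maps patch score maps (matrix, array, or list of
#'   matrices) with all scores in (0, 1); `real_maps` may be `NULL` on the
#'   generator side.
#' @param side `"discriminator"` or `"generator"`.
#' @return scalar loss (mean over patches, then batch).
#' @export
patch_adv_loss <- function(real_maps, fake_maps, side = "discriminator") {
  side <- adv_side(side)
  flat <- function(m) {
    v <- unlist(m, use.names = FALSE)
    assert_that(length(v) >= 1, "empty score batch")
    assert_that(all(v > 0 & v < 1), "scores must lie in (0, 1)")
    v
  }
  fake <- flat(fake_maps)
  if (side == "generator") return(-mean(log(pmax(fake, EPS_LOG))))
  real <- flat(real_maps)
  -mean(log(pmax(real, EPS_LOG))) - mean(log(pmax(1 - fake, EPS_LOG)))
}

#' Fourier adversarial loss of D3
#'
#' Same contract as [patch_adv_loss()] but over D3's scalar realness scores
#' of image spectra.  With the default magnitude-only spectrum, the loss is
#' invariant to circular image shifts (which change phase only).
#'
#' @param real_scores,fake_scores numeric score batches in (0, 1).
#' @param side `"discriminator"` or `"generator"`.
#' @return scalar loss.
#' @export
freq_adv_loss <- function(real_scores, fake_scores, side = "discriminator") {
  patch_adv_loss(real_scores, fake_scores, side)
}

#' Loss weights
#'
#' @param lambda_cls,lambda_adv,lambda_freq,lambda_clp nonnegative weights of
#'   the classification, patch-adversarial, Fourier-adversarial and
#'   contrastive terms; at least one must be positive.
#' @param lambda_rec nonnegative weight of the generator's L1 reconstruction
#'   term.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_cls = 1, lambda_adv = 1, lambda_freq = 1,
                         lambda_clp = 1, lambda_rec = 1) {
  w <- c(lambda_cls = lambda_cls, lambda_adv = lambda_adv,
         lambda_freq = lambda_freq, lambda_clp = lambda_clp,
         lambda_rec = lambda_rec)
  assert_that(all(is.finite(w)) && all(w >= 0), "loss weights must be nonnegative")
  assert_that(any(w[1:4] > 0), "at least one loss weight must be positive")
  structure(as.list(w), class = "loss_weights")
}

#' Aggregate weighted loss
#'
#' Combines the scalar loss components into the side total
#' `lambda_cls * cls + lambda_adv * adv_patch + lambda_freq * adv_freq +
#' lambda_clp * clp` (the generator side additionally adds
#' `lambda_rec * recon`).
#'
#' @param components named list with `clp`, `cls`, `adv_patch`, `adv_freq`
#'   and optionally `recon` (generator side).
#' @param weights a [loss_weights()].
#' @param side `"discriminator"` or `"generator"`.
#' @param tau temperature recorded in the report.
#' @return object of class `loss_report`.
#' @export
total_loss <- function(components, weights = loss_weights(),
                       side = "discriminator", tau = 0.5) {
  side <- adv_side(side)
  need <- c("clp", "cls", "adv_patch", "adv_freq")
  for (nm in need) {
    v <- components[[nm]]
    assert_that(!is.null(v) && length(v) == 1, "missing loss component '", nm, "'")
    if (!is.finite(v)) stop_input("non-finite loss component '", nm, "'")
  }
  recon <- components$recon %||% 0
  if (!is.finite(recon)) stop_input("non-finite loss component 'recon'")
  core <- weights$lambda_cls * components$cls +
    weights$lambda_adv * components$adv_patch +
    weights$lambda_freq * components$adv_freq +
    weights$lambda_clp * components$clp
  rep <- list(side = side, clp = components$clp, cls = components$cls,
              adv_patch = components$adv_patch, adv_freq = components$adv_freq,
              recon = if (side == "generator") recon else NA_real_,
              total_discriminator = if (side == "discriminator") core else NA_real_,
              total_generator = if (side == "generator") core + weights$lambda_rec * recon else NA_real_,
              tau = tau, weights = weights)
  structure(rep, class = "loss_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.loss_report <- function(x, ...) {
  tot <- if (x$side == "discriminator") x$total_discriminator else x$total_generator
  cat(sprintf("loss_report [%s]: total %.4f (clp %.4f, cls %.4f, patch %.4f, freq %.4f)\n",
              x$side, tot, x$clp, x$cls, x$adv_patch, x$adv_freq))
  invisible(x)
}

# one JSON-lines record per training step
loss_record <- function(step, report) {
  tot <- if (report$side == "discriminator") report$total_discriminator else report$total_generator
  jsonlite::toJSON(list(step = step, side = report$side, clp = report$clp,
                        cls = report$cls, adv_patch = report$adv_patch,
                        adv_freq = report$adv_freq, total = tot),
                   auto_unbox = TRUE, digits = NA)
}
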