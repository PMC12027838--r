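## Image-quality and diversity metrics.

gaussian_kernel2d <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

filt_valid <- function(x, k) {
  kb <- array(k, c(dim(k), 1L, 1L))
  b <- cpp_conv2d_fwd(as_batch(x), kb, 0, 1L, 0L)
  batch_to_matrix(b)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over 11 x 11 Gaussian-weighted windows (sigma 1.5) at all
#' fully-interior positions, with the conventional stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L = 1`.
#' Symmetric in its arguments; equals 1 exactly for identical images.
#'
#' @param a,b pixel matrices of equal shape with intensities in `[0, 1]`,
#'   at least 11 pixels on each side.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(all(dim(a) == dim(b)), "ssim: shape mismatch")
  assert_that(min(dim(a)) >= 11, "ssim: images must be at least 11 x 11")
  check_pixels(a, "a"); check_pixels(b, "b")
  k <- gaussian_kernel2d()
  mu_a <- filt_valid(a, k); mu_b <- filt_valid(b, k)
  va <- filt_valid(a * a, k) - mu_a^2
  vb <- filt_valid(b * b, k) - mu_b^2
  vab <- filt_valid(a * b, k) - mu_a * mu_b
  C1 <- 0.01^2; C2 <- 0.03^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / MSE)` with `MAX = 1`; identical images return the cap.
#'
#' @param a,b pixel matrices of equal shape with intensities in `[0, 1]`.
#' @param cap value in dB returned when the MSE is zero (default 100).
#' @return scalar in dB.
#' @export
psnr <- function(a, b, cap = 100) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(all(dim(a) == dim(b)), "psnr: shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  min(10 * log10(1 / mse), cap)
}

#' Frechet distance between two feature sets
#'
#' Fits a Gaussian to each feature set by its sample moments and returns
#' `||mu_a - mu_b||^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`.  With features
#' from a pluggable frozen extractor (here: penultimate features of a
#' phantom-trained D1 clone) this is an FID-style score; it is *not*
#' comparable to published Inception-FID numbers.
#'
#' @param features_a,features_b numeric matrices (rows = samples); a plain
#'   vector is treated as 1-D features.
#' @param ridge nonnegative ridge added to both covariance diagonals; needed
#'   when a set has fewer than `dim + 1` samples.
#' @return nonnegative scalar.
#' @export
fid_score <- function(features_a, features_b, ridge = 0) {
  fa <- if (is.matrix(features_a)) features_a else matrix(features_a, ncol = 1)
  fb <- if (is.matrix(features_b)) features_b else matrix(features_b, ncol = 1)
  assert_that(ncol(fa) == ncol(fb), "feature dimensions differ")
  d <- ncol(fa)
  if (ridge <= 0 && (nrow(fa) < d + 1 || nrow(fb) < d + 1))
    stop_input("need at least dim + 1 = ", d + 1,
               " samples per set for a nonsingular covariance; ",
               "supply ridge > 0 (e.g. ridge = 1e-6) to regularize")
  mu_a <- colMeans(fa); mu_b <- colMeans(fb)
  Sa <- stats::cov(fa) + diag(ridge, d)
  Sb <- stats::cov(fb) + diag(ridge, d)
  ea <- eigen((Sa + t(Sa)) / 2, symmetric = TRUE)
  sqa <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  M <- sqa %*% Sb %*% sqa
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  val <- sum((mu_a - mu_b)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * sum(sqrt(pmax(ev, 0)))
  max(val, 0)
}

#' Latent-space separation of embedding groups
#'
#' Measures how far apart groups of embeddings sit relative to their internal
#' spread: `between` is the mean pairwise distance between group centroids,
#' `within` the mean distance of members to their own centroid, and
#' `separation = between - within` (reported raw, not clipped).
#'
#' @param groups list of >= 2 numeric matrices (rows = embeddings), e.g. one
#'   matrix per source image or per class.
#' @return object of class `latent_distance` with `between`, `within`,
#'   `separation`.
#' @export
latent_distance <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2, "need at least 2 groups")
  groups <- lapply(groups, function(g) if (is.matrix(g)) g else matrix(g, nrow = 1))
  cent <- t(vapply(groups, colMeans, numeric(ncol(groups[[1]]))))
  nb <- 0; between <- 0
  for (i in seq_len(nrow(cent) - 1))
    for (j in seq.int(i + 1, nrow(cent))) {
      between <- between + sqrt(sum((cent[i, ] - cent[j, ])^2))
      nb <- nb + 1
    }
  between <- between / nb
  within <- mean(vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    mean(sqrt(rowSums((g - matrix(cent[i, ], nrow(g), ncol(g), byrow = TRUE))^2)))
  }, 0))
  structure(list(between = between, within = within,
                 separation = between - within),
            class = "latent_distance")
}

#' @export
print.latent_distance <- function(x, ...) {
  cat(sprintf("latent_distance: between %.4f, within %.4f, separation %.4f\n",
              x$between, x$within, x$separation))
  invisible(x)
}

#' Classification accuracy versus augmentation diversity level
#'
#' For each diversity level `k` (the number of generated variants appended
#' per training image), trains a fresh copy of the small D1-architecture
#' classifier on the augmented training set and reports its accuracy on the
#' held-out test set.  Level 0 is the unaugmented baseline.  Every level
#' gets the same fixed budget of gradient steps (see [train_classifier()]),
#' so appending exact duplicates leaves accuracy unchanged up to sampling
#' noise and any gain at higher levels is attributable to variant diversity.
#'
#' @param train,test lists of [image_sample()] objects.
#' @param generator a trained `dsclp_state` (from [fit()]), a `dsclp_model`,
#'   or a function `f(pixels, seed)` returning a variant pixel matrix (an
#'   identity function gives the duplicate-only control).
#' @param levels integer vector of diversity levels, each >= 0.
#' @param seed integer seed controlling augmentation and classifier training.
#' @param steps,batch_size,lr classifier training settings.
#' @param sigma_global,sigma_local generator noise scales used for variants.
#' @return named numeric vector: accuracy per level.
#' @export
diversity_eval <- function(train, test, generator, levels, seed = 1,
                           steps = 300, batch_size = 16, lr = 2e-3,
                           sigma_global = 0.5, sigma_local = 0.5) {
  assert_that(length(train) >= 1 && length(test) >= 1, "empty train or test set")
  assert_that(all(levels >= 0), "levels must be nonnegative")
  image_size <- nrow(train[[1]]$pixels)
  acc <- numeric(length(levels))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    aug <- make_variants(train, generator, lev, mix_seed(seed, 300 + lev),
                         sigma_global, sigma_local)
    clf <- train_classifier(c(train, aug), image_size = image_size,
                            steps = steps, batch_size = batch_size,
                            lr = lr, seed = mix_seed(seed, 777))
    acc[li] <- classifier_accuracy(clf, test)
  }
  names(acc) <- as.character(levels)
  acc
}

# `level` variants per sample from a state, model, or plain function
make_variants <- function(samples, generator, level, seed,
                          sigma_global = 0.5, sigma_local = 0.5) {
  if (level == 0) return(list())
  out <- vector("list", length(samples) * level)
  k <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (v in seq_len(level)) {
      sd_iv <- mix_seed(seed, i * 131 + v)
      px <- if (is.function(generator)) {
        generator(s$pixels, sd_iv)
      } else {
        mdl <- if (inherits(generator, "dsclp_state")) generator$model else generator
        generate(mdl, s$pixels, sigma_global, sigma_local, seed = sd_iv)$image
      }
      k <- k + 1L
      out[[k]] <- image_sample(px, s$label, sprintf("%s-v%d", s$id, v))
    }
  }
  out
}
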