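test_that("clp_loss matches the brute-force oracle on random batches", {
  set.seed(7)
  taus <- c(0.05, 0.5, 1, 5)
  for (rep in 1:100) {
    d <- sample(2:64, 1)
    nneg <- sample(1:31, 1)
    anchor <- rnorm(d); positive <- rnorm(d)
    negatives <- lapply(seq_len(nneg), function(i) rnorm(d))
    tau <- sample(taus, 1)
    expect_equal(clp_loss(anchor, positive, negatives, tau),
                 clp_oracle(anchor, positive, negatives, tau),
                 tolerance = 1e-6)
  }
})

test_that("uniform similarities force the log-batch-size loss", {
  # positive and all negatives colinear with the anchor: every similarity is 1
  anchor <- c(1, 0, 0)
  negatives <- list(2 * anchor, 3 * anchor, 0.5 * anchor)
  for (tau in c(0.05, 0.5, 1, 5))
    expect_equal(clp_loss(anchor, anchor, negatives, tau), log(4),
                 tolerance = 1e-9)
})

test_that("clp_loss closed form and scale invariance hold", {
  expect_equal(clp_loss(c(1, 0), c(1, 0), list(c(0, 1)), tau = 1),
               log(1 + exp(-1)), tolerance = 1e-9)
  set.seed(3)
  a <- rnorm(8); p <- rnorm(8); ns <- list(rnorm(8), rnorm(8))
  expect_equal(clp_loss(10 * a, p, ns, 0.5), clp_loss(a, p, ns, 0.5),
               tolerance = 1e-9)
  expect_equal(clp_loss(a, 0.01 * p, ns, 0.5), clp_loss(a, p, ns, 0.5),
               tolerance = 1e-9)
  expect_error(clp_loss(a, 0 * p, ns, 0.5), "zero-norm")
  expect_error(clp_loss(a, p, ns, 0), "tau")
  expect_error(clp_loss(a, p, list(), 1), "negative")
})

test_that("clp_loss is monotone in the similarities and sharpens with low tau", {
  emb <- function(s) c(s, sqrt(1 - s^2))   # unit vector at cosine s to (1,0)
  anchor <- c(1, 0)
  loss_at <- function(sp, sn, tau) clp_loss(anchor, emb(sp), list(emb(sn)), tau)
  h <- 1e-4
  # strictly decreasing in the positive similarity
  expect_lt(loss_at(0.5 + h, -0.2, 1), loss_at(0.5 - h, -0.2, 1))
  # strictly increasing in a negative similarity
  expect_gt(loss_at(0.5, -0.2 + h, 1), loss_at(0.5, -0.2 - h, 1))
  # lower temperature amplifies the sensitivity to the positive similarity
  # (checked in the hard-negative regime, where the anchor has not yet won;
  # with an easy positive the low-temperature softmax saturates instead)
  g1 <- (loss_at(0.5 + h, 0.6, 1) - loss_at(0.5 - h, 0.6, 1)) / (2 * h)
  g01 <- (loss_at(0.5 + h, 0.6, 0.1) - loss_at(0.5 - h, 0.6, 0.1)) / (2 * h)
  expect_gt(abs(g01), abs(g1))
})

test_that("classification_loss matches the naive oracle and the closed forms", {
  expect_equal(classification_loss(c(1, 0, 0, 0), 0), 0, tolerance = 1e-6)
  expect_equal(classification_loss(rep(0.25, 4), 2), log(4), tolerance = 1e-9)
  expect_equal(classification_loss(c(0.7, 0.1, 0.1, 0.1), 0), -log(0.7),
               tolerance = 1e-9)
  set.seed(11)
  for (i in 1:25) {
    p <- runif(4); p <- p / sum(p)
    lab <- sample(0:3, 1)
    v <- classification_loss(p, lab)
    expect_equal(v, ce_oracle(p, lab), tolerance = 1e-9)
    expect_gte(v, 0)
  }
  # batch version averages
  P <- rbind(c(0.7, 0.1, 0.1, 0.1), rep(0.25, 4))
  expect_equal(classification_loss(P, c(0L, 1L)),
               mean(c(-log(0.7), log(4))), tolerance = 1e-9)
  expect_error(classification_loss(c(0.7, 0.1, 0.1, 0.1), 4), "range")
})

test_that("adversarial losses follow the non-saturating GAN convention", {
  half <- matrix(0.5, 4, 4)
  expect_equal(patch_adv_loss(half, half, "discriminator"), 2 * log(2),
               tolerance = 1e-9)
  expect_equal(patch_adv_loss(NULL, half, "generator"), log(2),
               tolerance = 1e-9)
  strong <- patch_adv_loss(matrix(0.999, 4, 4), matrix(0.001, 4, 4),
                           "discriminator")
  expect_lt(strong, 3e-3)   # -2 log(0.999) = 0.002001
  expect_gt(strong, 0)
  expect_error(patch_adv_loss(half, matrix(1.5, 2, 2), "discriminator"), "0, 1")
  expect_error(patch_adv_loss(half, numeric(0), "discriminator"), "empty")

  expect_equal(freq_adv_loss(rep(0.5, 8), rep(0.5, 8), "discriminator"),
               2 * log(2), tolerance = 1e-9)
  expect_equal(freq_adv_loss(NULL, rep(0.5, 8), "generator"), log(2),
               tolerance = 1e-9)
})

test_that("the Fourier loss ignores circular shifts (magnitude-only D3)", {
  m <- model32()
  x <- phantoms32(1, 14)[[1]]$pixels
  xs <- x[c(9:32, 1:8), c(20:32, 1:19)]   # circular shift changes phase only
  s1 <- d3_freq(m, spectral_transform(x))
  s2 <- d3_freq(m, spectral_transform(xs))
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_equal(freq_adv_loss(s1, 0.5, "discriminator"),
               freq_adv_loss(s2, 0.5, "discriminator"), tolerance = 1e-9)
})

test_that("total_loss aggregates with the lambda weights", {
  w <- loss_weights()
  r <- total_loss(list(clp = 0.5, cls = 0, adv_patch = 0, adv_freq = 0),
                  loss_weights(0, 0, 0, 1), "discriminator")
  expect_equal(r$total_discriminator, 0.5, tolerance = 1e-12)
  r0 <- total_loss(list(clp = 1, cls = 1, adv_patch = 1, adv_freq = 1),
                   loss_weights(0, 0, 0, 1e-12), "discriminator")
  expect_lt(r0$total_discriminator, 1e-11)

  comps <- list(clp = 0.3133, cls = 0.3567, adv_patch = 1.3863,
                adv_freq = 1.3863)
  r <- total_loss(comps, w, "discriminator")
  expect_equal(r$total_discriminator,
               0.3133 + 0.3567 + 1.3863 + 1.3863, tolerance = 1e-9)

  # linear in each lambda
  set.seed(5)
  comps <- list(clp = runif(1), cls = runif(1), adv_patch = runif(1),
                adv_freq = runif(1))
  base <- total_loss(comps, loss_weights(1, 1, 1, 1), "discriminator")
  dbl <- total_loss(comps, loss_weights(2, 1, 1, 1), "discriminator")
  expect_equal(dbl$total_discriminator - base$total_discriminator,
               comps$cls, tolerance = 1e-9)

  # report invariant: the total is the lambda-weighted sum of its parts
  for (i in 1:20) {
    cc <- list(clp = runif(1, 0, 3), cls = runif(1, 0, 3),
               adv_patch = runif(1, 0, 3), adv_freq = runif(1, 0, 3))
    ww <- loss_weights(runif(1), runif(1), runif(1), runif(1) + 0.01)
    rr <- total_loss(cc, ww, "discriminator")
    expect_lt(abs(rr$total_discriminator -
                    (ww$lambda_cls * cc$cls + ww$lambda_adv * cc$adv_patch +
                     ww$lambda_freq * cc$adv_freq + ww$lambda_clp * cc$clp)),
              1e-6)
  }

  expect_error(total_loss(list(clp = NaN, cls = 1, adv_patch = 1,
                               adv_freq = 1), w, "generator"), "clp")
})
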