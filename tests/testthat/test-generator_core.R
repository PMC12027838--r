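test_that("encode is total, deterministic, and does not collapse at init", {
  m <- model32()
  z0 <- encode(m, matrix(0, 32, 32))
  z1 <- encode(m, matrix(1, 32, 32))
  expect_length(c(z0$global_part, z0$local_part), 100)
  expect_true(all(is.finite(c(z0$global_part, z0$local_part,
                              z1$global_part, z1$local_part))))
  x <- phantoms32(1, 5)[[1]]$pixels
  expect_identical(encode(m, x), encode(m, x))
  Z <- t(vapply(phantoms32(32, 6), function(s) {
    z <- encode(m, s$pixels); c(z$global_part, z$local_part)
  }, numeric(100)))
  expect_true(all(apply(Z, 2, var) > 0))
  expect_error(encode(m, matrix(0.5, 16, 16)), "size")
})

test_that("perturb is the identity at zero noise and seed-deterministic", {
  z <- latent_code(rnorm(50), rnorm(50))
  expect_identical(perturb(z, 0, 0, seed = 99), z)
  expect_identical(perturb(z, 1, 1, seed = 5), perturb(z, 1, 1, seed = 5))
  expect_false(identical(perturb(z, 1, 1, seed = 5), perturb(z, 1, 1, seed = 6)))
  expect_error(perturb(z, -1, 0, seed = 1), "nonnegative")
})

test_that("the empirical mean of many perturbations recovers the code", {
  z <- latent_code(seq(-1, 1, length.out = 50), seq(1, -1, length.out = 50))
  n <- 10000
  sums <- numeric(100)
  for (s in seq_len(n)) {
    p <- perturb(z, 1, 1, seed = s)
    sums <- sums + c(p$global_part, p$local_part)
  }
  dev <- abs(sums / n - c(z$global_part, z$local_part))
  expect_true(all(dev < 4 / sqrt(n)))
})

test_that("the projection head is deterministic with unit self-similarity", {
  m <- model32()
  z <- latent_code(rnorm(50), rnorm(50))
  e1 <- project(m, z)
  expect_length(e1, 32)
  expect_identical(e1, project(m, z))
  expect_equal(sum(e1 * e1) / sum(e1^2), 1.0)
  sims <- c()
  set.seed(42)
  E <- t(vapply(1:16, function(i)
    project(m, latent_code(rnorm(50), rnorm(50))), numeric(32)))
  En <- E / sqrt(rowSums(E^2))
  S <- En %*% t(En)
  off <- S[upper.tri(S)]
  expect_gt(max(off) - min(off), 1e-6)   # not all pairwise sims equal
})

test_that("decode respects shapes and all decoder parameters get gradients", {
  m <- model32()
  x <- phantoms32(1, 7)[[1]]$pixels
  z <- encode(m, x, with_skips = TRUE)
  skips <- attr(z, "skips")
  out <- decode(m, z$global_part, z$local_part, skips)
  expect_identical(dim(out$image), c(32L, 32L))
  out0 <- decode(m, rep(0, 50), rep(0, 50),
                 list(skip1 = 0 * skips$skip1, skip2 = 0 * skips$skip2))
  expect_true(all(is.finite(out0$image)))
  expect_error(decode(m, z$global_part, z$local_part,
                      list(skip1 = skips$skip2, skip2 = skips$skip1)), "shape")

  # gradient of the output sum w.r.t. every decoder parameter group
  ns <- asNamespace("dsclpgan")
  tp <- ns$new_tape()
  P <- ns$param_nodes(tp, m$params)
  ba <- ns$batch_arrays(phantoms32(4, 8))
  enc <- ns$enc_forward(tp, P, m$cfg, ns$t_const(tp, ba$xb))
  dec <- ns$dec_forward(tp, P, m$cfg,
                        ns$op_cols(tp, enc$z, 1:50), ns$op_cols(tp, enc$z, 51:100),
                        enc$skip1, enc$skip2)
  tot <- ns$op_mean(tp, ns$op_add(tp, dec$gs, dec$gl))
  ns$tape_backward(tp, tot)
  for (nm in grep("^(dg|dl)_", names(m$params), value = TRUE)) {
    g <- P[[nm]]$grad
    expect_false(is.null(g), info = nm)
    expect_gt(sum(abs(g)), 0)
  }
})

test_that("generate composes encode-perturb-decode deterministically", {
  m <- model32()
  x <- phantoms32(1, 9)[[1]]$pixels
  expect_equal(generate(m, x, 0, 0, seed = 1)$image,
               generate(m, x, 0, 0, seed = 2)$image)   # zero noise: seed-free
  g1 <- generate(m, x, 0.5, 0.5, seed = 1)
  expect_identical(g1$image, generate(m, x, 0.5, 0.5, seed = 1)$image)
  expect_gte(min(g1$image), 0)
  expect_lte(max(g1$image), 1)
  # bounded for extreme latent noise too
  gx <- generate(m, x, 25, 25, seed = 3)$image
  expect_true(all(gx >= 0 & gx <= 1 & is.finite(gx)))
})

test_that("image equals the bounded activation of the summed components", {
  m <- model32()
  x <- phantoms32(1, 10)[[1]]$pixels
  g <- generate(m, x, 0.5, 0.5, seed = 4)
  pre <- g$global_component + g$local_component
  expect_lt(max(abs(1 / (1 + exp(-pre)) - g$image)), 1e-6)
})

test_that("seeded variants of one input are diverse", {
  m <- model32()
  x <- phantoms32(1, 11)[[1]]$pixels
  outs <- lapply(1:5, function(s) generate(m, x, 0.5, 0.5, seed = s)$image)
  d <- utils::combn(5, 2, function(ij)
    sqrt(mean((outs[[ij[1]]] - outs[[ij[2]]])^2)))
  expect_gt(mean(d), 0)
})

test_that("tape gradients agree with central finite differences", {
  ns <- asNamespace("dsclpgan")
  m <- dsclp_model(image_size = 32, seed = 4)
  cfg <- m$cfg
  tcfg <- train_config(image_size = 32, batch_size = 4, seed = 3)
  ba <- ns$batch_arrays(phantoms32(4, 12))
  p1 <- ns$make_stream_noise(4, cfg, 0.5, 0.5, 21)
  p2 <- ns$make_stream_noise(4, cfg, 0.5, 0.5, 22)
  loss_val <- function(params) {
    gt <- ns$g_tape(params, cfg, tcfg, ba$xb, ba$labels, p1, p2)
    as.numeric(gt$total$value)
  }
  gt <- ns$g_tape(m$params, cfg, tcfg, ba$xb, ba$labels, p1, p2)
  ns$tape_backward(gt$tp, gt$total)
  eps <- 1e-4
  check <- c("enc_c1_W", "enc_fc_W", "prj_fc2_W", "dg_fc_W", "dg_out_W",
             "dl_c1_W", "d1_fc2_W", "d2_out_W", "d3_fc_W")
  for (nm in check) {
    g <- gt$P[[nm]]$grad
    i <- which.max(abs(g))
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss_val(pp)
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] - eps; dn <- loss_val(pp)
    fd <- (up - dn) / (2 * eps)
    # tolerance accommodates finite-difference noise at leaky-ReLU kinks
    expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-8), 5e-2,
              label = paste("relative gradient error for", nm))
  }
})

test_that("global-stream noise drives lower-frequency change than local", {
  # directional architecture property, evaluated on smoke-trained models
  votes <- 0L
  for (seed in 1:3) {
    st <- smoke_state(seed)
    dat <- memo("smoke_data", make_dataset(default_spec(), 256, 11))
    rg <- c(); rl <- c()
    for (i in 1:32) {
      x <- dat[[i]]$pixels
      base <- generate(st$model, x, 0, 0, seed = 1)$image
      og <- generate(st$model, x, 0.5, 0, seed = i + 7)$image
      ol <- generate(st$model, x, 0, 0.5, seed = i + 7)$image
      rg <- c(rg, lowfreq_fraction(og - base))
      rl <- c(rl, lowfreq_fraction(ol - base))
    }
    if (mean(rg) > mean(rl)) votes <- votes + 1L
  }
  expect_gte(votes, 2L)
})
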