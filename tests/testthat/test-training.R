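small_cfg <- function(seed = 1, epochs = 1, batch_size = 4, ...) {
  train_config(preset = "desk", image_size = 32, batch_size = batch_size,
               epochs = epochs, seed = seed, ...)
}

test_that("a zero learning-rate step leaves all parameters untouched", {
  st <- init_state(small_cfg(learning_rate = 0))
  res <- train_step(st, phantoms32(4, 21))
  expect_identical(res$state$model$params, st$model$params)
})

test_that("train_step is deterministic and loss reports are finite", {
  batch <- phantoms32(4, 22)
  r1 <- train_step(init_state(small_cfg(seed = 3)), batch)
  r2 <- train_step(init_state(small_cfg(seed = 3)), batch)
  expect_identical(r1$state$model$params, r2$state$model$params)
  for (f in c("clp", "cls", "adv_patch", "adv_freq")) {
    expect_true(is.finite(r1$d_report[[f]]))
    expect_true(is.finite(r1$g_report[[f]]))
  }
  expect_true(is.finite(r1$d_report$total_discriminator))
  expect_true(is.finite(r1$g_report$total_generator))
})

test_that("every generator parameter group receives gradient signal", {
  st <- init_state(train_config(preset = "desk", seed = 1))
  audit <- gradient_audit(st, phantoms64(16, 23))
  expect_setequal(audit$param,
                  grep("^(enc|prj|dg|dl)_", names(st$model$params), value = TRUE))
  expect_true(all(audit$norm > 0))
  overall_zero <- sum(audit$frac_zero * audit$n) / sum(audit$n)
  expect_lt(overall_zero, 0.5)
})

test_that("optimizer updates are segregated by side", {
  ns <- asNamespace("dsclpgan")
  st <- init_state(small_cfg())
  p <- st$model$params
  fake_grads <- lapply(p, function(v) array(1, if (is.null(dim(v))) length(v) else dim(v)))
  dn <- ns$d_param_names(p)
  gn <- ns$g_param_names(p)
  expect_length(intersect(dn, gn), 0)
  expect_setequal(c(dn, gn), names(p))
  up <- ns$adam_step(p, fake_grads, ns$adam_new(p[dn]), dn, 1e-3, 0.5, 0.999)
  expect_identical(up$params[gn], p[gn])          # generator untouched
  expect_false(any(vapply(dn, function(nm)
    identical(up$params[[nm]], p[[nm]]), TRUE)))  # all discriminators moved
})

test_that("non-finite losses abort with the offending term named", {
  st <- init_state(small_cfg())
  st$model$params$enc_fc_W[] <- NaN
  expect_error(train_step(st, phantoms32(4, 24)), "non-finite loss term")
})

test_that("fit produces a finite history with a pre-training baseline row", {
  dat <- phantoms32(48, 25)
  st <- fit(dat, small_cfg(seed = 2, epochs = 2))
  h <- st$history
  expect_identical(h$epoch, 0:2)
  expect_true(all(is.finite(h$val_ssim)))
  expect_true(all(is.finite(h$val_psnr)))
  expect_true(all(is.finite(as.matrix(h[-1, c("d_total", "g_total", "clp",
                                              "cls", "adv_patch", "adv_freq",
                                              "recon")]))))
})

test_that("checkpoints round-trip and refuse foreign formats", {
  dat <- phantoms32(16, 26)
  td <- withr::local_tempdir()
  st <- fit(dat, small_cfg(seed = 4, batch_size = 4), checkpoint_dir = td)
  expect_true(file.exists(file.path(td, "epoch-001.rds")))
  f <- file.path(td, "final.rds")
  save_checkpoint(st, f)
  st2 <- load_checkpoint(f)
  expect_identical(st2$model$params, st$model$params)
  expect_identical(st2$config, st$config)
  # resumed training continues identically from the restored state
  b <- phantoms32(4, 27)
  expect_identical(train_step(st, b)$state$model$params,
                   train_step(st2, b)$state$model$params)
  bad <- file.path(td, "bad.rds")
  saveRDS(list(format = "something-else", state = list()), bad)
  expect_error(load_checkpoint(bad), "format")
})

test_that("augment_dataset preserves labels and scales counts exactly", {
  st <- init_state(small_cfg())
  ds <- phantoms32(10, 28)
  expect_identical(augment_dataset(ds, st, 0), ds)
  aug <- augment_dataset(ds, st, 3, seed = 2)
  expect_length(aug, 40)
  base_tab <- table(vapply(ds, `[[`, 0L, "label"))
  aug_tab <- table(vapply(aug, `[[`, 0L, "label"))
  expect_identical(as.integer(aug_tab), as.integer(base_tab) * 4L)
  # variants of the same image differ pairwise under nonzero noise
  v <- aug[11:40]
  src1 <- v[grepl(paste0("^", ds[[1]]$id, "-"), vapply(v, `[[`, "", "id"))]
  expect_length(src1, 3)
  d12 <- mean((src1[[1]]$pixels - src1[[2]]$pixels)^2)
  d13 <- mean((src1[[1]]$pixels - src1[[3]]$pixels)^2)
  expect_gt(d12, 0); expect_gt(d13, 0)
  expect_error(augment_dataset(ds, st, -1), "nonnegative")
})
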