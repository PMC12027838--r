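test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- default_spec()
  a <- make_phantom(spec, 2, seed = 7)
  b <- make_phantom(spec, 2, seed = 7)
  expect_identical(a$pixels, b$pixels)
  d1 <- make_dataset(spec, 5, seed = 1)
  d2 <- make_dataset(spec, 5, seed = 1)
  d3 <- make_dataset(spec, 5, seed = 2)
  expect_identical(lapply(d1, `[[`, "pixels"), lapply(d2, `[[`, "pixels"))
  expect_false(identical(lapply(d1, `[[`, "pixels"), lapply(d3, `[[`, "pixels")))
})

test_that("per-sample substreams do not depend on dataset size", {
  spec <- default_spec()
  d10 <- make_dataset(spec, 10, seed = 5)
  d3 <- make_dataset(spec, 3, seed = 5)
  for (i in 1:3) expect_identical(d10[[i]]$pixels, d3[[i]]$pixels)
})

test_that("the no-tumor class has no lesion and tumor classes do", {
  spec <- default_spec()
  # brain texture tops out near 0.60; lesions rise well above it
  for (s in 1:8) expect_lt(max(make_phantom(spec, 0, s)$pixels), 0.70)
  for (lab in 1:3) for (s in 1:8) {
    ph <- make_phantom(spec, lab, s)
    mask <- ph$meta$lesion_mask
    expect_gt(sum(mask), 0)
    brain <- ph$pixels > 0.1 & !mask
    expect_gt(mean(ph$pixels[mask]), mean(ph$pixels[brain]))
  }
})

test_that("meningioma-analog lesions are eccentric (rim prior)", {
  ph <- make_phantom(default_spec(), 1, seed = 3)
  hot <- which(ph$pixels > 0.70, arr.ind = TRUE)
  expect_gt(nrow(hot), 0)
  ctr <- (64 + 1) / 2
  centroid_dist <- sqrt((mean(hot[, 1]) - ctr)^2 + (mean(hot[, 2]) - ctr)^2)
  expect_gte(centroid_dist, 0.25 * 64)
})

test_that("dataset labels follow the class probabilities", {
  one_class <- phantom_spec(class_probs = c(1, 0, 0, 0))
  d <- make_dataset(one_class, 10, seed = 1)
  expect_true(all(vapply(d, `[[`, 0L, "label") == 0L))

  d <- phantoms64(1000, 2)
  labs <- vapply(d, `[[`, 0L, "label")
  for (k in 0:3) {
    p <- 0.25
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(mean(labs == k) - p), 4 * se)
  }
})

test_that("generated samples satisfy the image invariants", {
  d <- phantoms64(200, 13)
  for (s in d) {
    expect_true(all(is.finite(s$pixels)))
    expect_gte(min(s$pixels), 0)
    expect_lte(max(s$pixels), 1)
    expect_identical(dim(s$pixels), c(64L, 64L))
    expect_true(s$label %in% 0:3)
  }
  expect_identical(anyDuplicated(vapply(d, `[[`, "", "id")), 0L)
})

test_that("classes are separable by a histogram nearest-centroid classifier", {
  d <- memo("sep500", make_dataset(default_spec(), 500, 21))
  feats <- t(vapply(d, function(s)
    hist(s$pixels, breaks = seq(0, 1, by = 0.05), plot = FALSE)$counts / 4096,
    numeric(20)))
  labs <- vapply(d, `[[`, 0L, "label")
  tr <- 1:250; te <- 251:500
  mu <- colMeans(feats[tr, ])
  sdv <- pmax(apply(feats[tr, ], 2, sd), 1e-8)
  ztr <- sweep(sweep(feats[tr, ], 2, mu), 2, sdv, "/")
  zte <- sweep(sweep(feats[te, ], 2, mu), 2, sdv, "/")
  cent <- sapply(0:3, function(k) colMeans(ztr[labs[tr] == k, , drop = FALSE]))
  pred <- apply(zte, 1, function(f) which.min(colSums((cent - f)^2)) - 1)
  expect_gt(mean(pred == labs[te]), 0.5)
})

test_that("invalid phantom inputs are rejected", {
  spec <- default_spec()
  expect_error(make_phantom(spec, 5, 1), "label")
  expect_error(make_phantom(spec, -1, 1), "label")
  expect_error(make_dataset(spec, 0, 1), "n must be")
  expect_error(phantom_spec(class_probs = c(1, 1, 0, 0)), "sum to 1")
  expect_error(phantom_spec(lesion_radius_range = list(`1` = c(0, 0),
                                                       `2` = c(7, 11),
                                                       `3` = c(2.5, 4.5))),
               "positive")
  expect_error(phantom_spec(image_size = 48), "power of two")
})

test_that("PNG output round-trips byte-identically and NIfTI preserves values", {
  d <- make_dataset(default_spec(), 3, 4)
  td <- withr::local_tempdir()
  write_images(d, file.path(td, "a"), "png")
  rd <- read_image_dir(file.path(td, "a"))
  write_images(rd, file.path(td, "b"), "png")
  for (s in d) {
    fa <- file.path(td, "a", paste0(s$id, ".png"))
    fb <- file.path(td, "b", paste0(s$id, ".png"))
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
  }
  lab <- utils::read.csv(file.path(td, "a", "labels.csv"))
  expect_identical(names(lab), c("id", "label", "file"))
  expect_identical(lab$label, vapply(d, `[[`, 0L, "label"))

  write_images(d, file.path(td, "n"), "nifti")
  rn <- read_image_dir(file.path(td, "n"))
  expect_equal(rn[[1]]$pixels, d[[1]]$pixels, tolerance = 1e-12)
  expect_identical(rn[[2]]$label, d[[2]]$label)
})
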