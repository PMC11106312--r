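test_that("phantom generation is a pure function of spec and seed", {
  spec <- tiny_spec(image_size = 64L)
  a <- generate_ct_phantom(spec, 7)
  b <- generate_ct_phantom(spec, 7)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, generate_ct_phantom(spec, 8)$pixels))
  expect_s3_class(a, "domain_image")
  expect_equal(a$domain, "B_ct")
  expect_equal(a$scale, "hu_like")
})

test_that("a structure-free phantom contains exactly air and soft tissue", {
  spec <- tiny_spec(image_size = 64L, n_structures = 0L)
  img <- generate_ct_phantom(spec, 1)
  vals <- sort(unique(as.vector(img$pixels)))
  expect_length(vals, 2L)
  expect_equal(vals[1], -1000)
  ic <- spec$intensity_classes
  expect_equal(vals[2], ic$mean[ic$label == "soft_tissue"])
})

test_that("phantoms with several structures include bone-class pixels", {
  # oracle: scan for pixels inside the bone class interval mean +/- spread
  spec <- phantom_spec(image_size = 64L, n_structures = 5L)
  img <- generate_ct_phantom(spec, 3)
  ic <- spec$intensity_classes
  bone <- ic[ic$label == "bone", ]
  n_bone <- sum(img$pixels >= bone$mean - bone$spread &
                img$pixels <= bone$mean + bone$spread)
  expect_gt(n_bone, 0)
})

test_that("invalid phantom specs fail naming the offending field", {
  expect_error(phantom_spec(image_size = 16L), "image_size")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(n_streaks = -2), "n_streaks")
  bad <- default_intensity_classes()
  bad$mean <- rev(bad$mean)
  expect_error(phantom_spec(intensity_classes = bad), "increasing")
  expect_error(generate_ct_phantom(list(), 1), "phantom_spec")
})

test_that("body mask is the filled largest component above the air threshold", {
  soft <- domain_image(matrix(50, 32, 32), "B_ct", "hu_like")
  expect_equal(sum(generate_body_mask(soft, -500)), 32 * 32)
  air <- domain_image(matrix(-1000, 32, 32), "B_ct", "hu_like")
  expect_error(generate_body_mask(air, -500), "empty mask")
})

test_that("mask area matches the analytic body-ellipse area", {
  # pinned seed: body ellipse fully interior and no air cavity crosses the
  # body boundary (a boundary cavity legitimately notches the contour)
  spec <- phantom_spec(image_size = 64L, n_structures = 5L)
  img <- generate_ct_phantom(spec, 5)
  mask <- generate_body_mask(img)
  be <- attr(img, "body_ellipse")
  analytic <- pi * be$a * be$b
  expect_lt(abs(sum(mask) - analytic), 0.02 * 64^2)
})

test_that("degradation with all amplitudes zero is the identity", {
  spec <- phantom_spec(image_size = 64L, cupping_amplitude = 0, n_streaks = 0L,
                       streak_amplitude = 0, noise_sigma = 0, blur_sigma = 0)
  ct <- generate_ct_phantom(spec, 2)
  out <- degrade_to_cbct(ct, spec, 9)
  expect_identical(out$pixels, ct$pixels)
  expect_equal(out$domain, "A_cbct")
})

test_that("noise-only degradation has the stated moments", {
  # oracle: sample moments of the drawn field; n = 256^2
  spec <- phantom_spec(image_size = 256L, cupping_amplitude = 0, n_streaks = 0L,
                       noise_sigma = 50, blur_sigma = 0)
  ct <- generate_ct_phantom(spec, 4)
  out <- degrade_to_cbct(ct, spec, 5)
  resid <- out$pixels - ct$pixels
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 50 / sqrt(n))
  expect_lt(abs(sd(resid) - 50) / 50, 0.05)
})

test_that("cupping-only residual drops by exactly the amplitude centre-to-corner", {
  # oracle: the quadratic bowl evaluated at the centre and corner pixels
  spec <- phantom_spec(image_size = 65L, cupping_amplitude = 100, n_streaks = 0L,
                       noise_sigma = 0, blur_sigma = 0)
  ct <- generate_ct_phantom(spec, 4)
  out <- degrade_to_cbct(ct, spec, 5)
  resid <- out$pixels - ct$pixels
  centre <- resid[33, 33]
  corner <- resid[1, 1]
  expect_lt(abs((centre - corner) - (-100)), 1e-6)
})

test_that("degradation is seeded deterministically and streaks obey their bound", {
  spec <- phantom_spec(image_size = 64L)
  ct <- generate_ct_phantom(spec, 2)
  expect_identical(degrade_to_cbct(ct, spec, 3)$pixels,
                   degrade_to_cbct(ct, spec, 3)$pixels)
  spec_s <- phantom_spec(image_size = 64L, cupping_amplitude = 0, n_streaks = 4L,
                         streak_amplitude = 80, noise_sigma = 0, blur_sigma = 0)
  resid <- degrade_to_cbct(ct, spec_s, 3)$pixels - ct$pixels
  expect_lte(max(abs(resid)), 80 * 4 + 1e-9)
  expect_gt(sum(resid != 0), 0)
})

test_that("dataset bundles have the contracted structure and reproducibility", {
  spec <- tiny_spec()
  ds <- build_dataset(spec, n_train_per_domain = 10, n_test = 2, seed = 5)
  expect_length(ds$train_A, 10)
  expect_length(ds$train_B, 10)
  expect_length(ds$test_pairs, 2)
  expect_true(all(vapply(ds$train_A, function(x) x$domain, "") == "A_cbct"))
  expect_true(all(vapply(ds$train_B, function(x) x$domain, "") == "B_ct"))
  ds2 <- build_dataset(spec, 10, 2, seed = 5)
  for (i in seq_len(10)) {
    expect_identical(ds$train_A[[i]]$pixels, ds2$train_A[[i]]$pixels)
    expect_identical(ds$train_B[[i]]$pixels, ds2$train_B[[i]]$pixels)
  }
  expect_error(build_dataset(spec, 10, 0, seed = 1), "n_test")
})

test_that("test pairs are aligned and masking their interiors is a no-op", {
  ds <- build_dataset(tiny_spec(), 4, 2, seed = 11)
  for (p in ds$test_pairs) {
    expect_equal(dim(p$A$pixels), dim(p$B$pixels))
    expect_equal(dim(p$mask), dim(p$A$pixels))
    inside <- p$mask == 1
    expect_equal(apply_mask(p$B, p$mask)$pixels[inside], p$B$pixels[inside])
    expect_equal(apply_mask(p$A, p$mask)$pixels[inside], p$A$pixels[inside])
  }
})

test_that("degradation opens a positive masked MAE gap for training to close", {
  ds <- build_dataset(tiny_spec(image_size = 64L), 2, 3, seed = 13)
  for (p in ds$test_pairs) {
    expect_gt(metric_mae(p$B, p$A, masks = p$mask), 0)
  }
})
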