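test_that("MAE matches brute-force sums", {
  x <- rand_image(8, seed = 1)
  expect_equal(metric_mae(x, x), 0)
  expect_equal(metric_mae(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- matrix(c(0, 5, 1, 4), 2, 2)
  a2 <- matrix(c(-1, 0, 2, 2), 2, 2)
  b2 <- matrix(c(1, 0, 0, 0), 2, 2)
  want <- (sum(abs(a - b)) + sum(abs(a2 - b2))) / 8
  expect_equal(metric_mae(list(a, a2), list(b, b2)), want)
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(metric_mae(a, b, masks = m), mean(abs(a - b)[m == 1]))
  expect_error(metric_mae(list(a), list(b, b2)), "count mismatch")
})

test_that("PSNR implements both conventions and the identical-image sentinel", {
  x <- matrix(0, 10, 10)
  y <- matrix(0.1, 10, 10)   # MSE = 0.01
  expect_equal(metric_psnr(x, y, "standard", max_value = 1), 20)
  expect_equal(metric_psnr(x, y, "as_printed", max_value = 1), 40)
  same <- metric_psnr(x, x)
  expect_true(is.infinite(same))
  expect_true(attr(same, "identical"))
})

test_that("standard PSNR strictly decreases as MSE increases", {
  x <- matrix(0, 8, 8)
  vals <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6),
                 function(s) metric_psnr(x, matrix(s, 8, 8), max_value = 1),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM equals 1 on identical images and its constant closed form", {
  x <- rand_image(16, seed = 2, lo = 0, hi = 1)
  expect_equal(metric_ssim(x, x, data_range = 1), 1, tolerance = 1e-12)
  a <- 0.3; b <- 0.6
  c1 <- (0.01)^2
  want <- (2 * a * b + c1) / (a^2 + b^2 + c1)
  got <- metric_ssim(matrix(a, 8, 8), matrix(b, 8, 8), data_range = 1,
                     window_size = NULL)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("windowed SSIM matches an independent sliding-window implementation", {
  brute_ssim <- function(x, y, L, win = 11L, sigma = 1.5) {
    half <- (win - 1) / 2
    g <- exp(-((-half:half)^2) / (2 * sigma^2))
    k <- outer(g, g); k <- k / sum(k)
    c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
    vals <- c()
    for (i in seq_len(nrow(x) - win + 1)) {
      for (j in seq_len(ncol(x) - win + 1)) {
        px <- x[i:(i + win - 1), j:(j + win - 1)]
        py <- y[i:(i + win - 1), j:(j + win - 1)]
        mx <- sum(k * px); my <- sum(k * py)
        vx <- sum(k * px^2) - mx^2; vy <- sum(k * py^2) - my^2
        cxy <- sum(k * px * py) - mx * my
        vals <- c(vals, (2 * mx * my + c1) * (2 * cxy + c2) /
                          ((mx^2 + my^2 + c1) * (vx + vy + c2)))
      }
    }
    mean(vals)
  }
  x <- rand_image(16, seed = 3, lo = 0, hi = 1)
  y <- 0.7 * x + 0.1 + 0.2 * rand_image(16, seed = 4, lo = 0, hi = 1)
  expect_equal(metric_ssim(x, y, data_range = 1),
               brute_ssim(x, y, 1), tolerance = 1e-6)
  # symmetry
  expect_equal(metric_ssim(x, y, data_range = 1),
               metric_ssim(y, x, data_range = 1), tolerance = 1e-12)
  expect_lt(metric_ssim(x, y, data_range = 1), 1)
})

test_that("evaluate_pairs aggregates per-slice metrics inside the mask", {
  ct <- generate_ct_phantom(tiny_spec(), 2)
  mask <- generate_body_mask(ct)
  pairs <- list(list(A = domain_image(ct$pixels, "A_cbct", "hu_like"),
                     B = ct, mask = mask),
                list(A = domain_image(ct$pixels, "A_cbct", "hu_like"),
                     B = ct, mask = mask))
  rep_ <- evaluate_pairs(pairs, function(img) img)
  expect_equal(rep_$n_slices, 2)
  expect_equal(rep_$mae, 0)
  expect_equal(rep_$ssim, 1, tolerance = 1e-12)
  expect_equal(nrow(rep_$per_slice), 2)

  # out-of-mask noise changes unmasked but not masked evaluation
  noisy <- ct$pixels
  noisy[mask == 0] <- noisy[mask == 0] + 300
  pairs_n <- list(list(A = domain_image(noisy, "A_cbct", "hu_like"),
                       B = ct, mask = mask))
  masked <- evaluate_pairs(pairs_n, function(img) img, masked = TRUE)
  unmasked <- evaluate_pairs(pairs_n, function(img) img, masked = FALSE)
  expect_lt(masked$mae, unmasked$mae)
})

test_that("HU histograms count what the mask admits", {
  img <- domain_image(matrix(0, 8, 8), "B_ct", "hu_like")
  h <- hu_histogram(img, bins = 10L)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(sum(h$count), 64)
  mask <- matrix(0L, 8, 8); mask[1:4, ] <- 1L
  h2 <- hu_histogram(img, masks = mask, bins = 10L)
  expect_equal(sum(h2$count), 32)
  # a uniform ramp over the range fills bins nearly evenly
  ramp <- domain_image(matrix(seq(-499.9, 499.9, length.out = 10000), 100, 100),
                       "B_ct", "hu_like")
  h3 <- hu_histogram(ramp, bins = 20L)
  expect_lt(max(h3$count) - min(h3$count), 0.05 * mean(h3$count) + 2)
})

test_that("axis profiles trace mean intensities per row and column", {
  const <- matrix(0.5, 16, 16)
  p <- axis_profiles(const)
  expect_length(p$row, 16)
  expect_length(p$col, 16)
  expect_true(all(abs(p$row - 0.5) < 1e-12))
  bright <- matrix(0, 16, 16); bright[5, ] <- 10
  p2 <- axis_profiles(bright)
  expect_equal(which.max(p2$row), 5L)
  expect_true(all(abs(p2$col - p2$col[1]) < 1e-12))
})

test_that("difference maps are antisymmetric and render to PNG", {
  a <- rand_image(8, seed = 5)
  b <- rand_image(8, seed = 6)
  expect_true(all(difference_map(a, a)$signed == 0))
  expect_equal(difference_map(a, b)$signed, -difference_map(b, a)$signed)
  expect_equal(max(difference_map(a, b)$abs), max(abs(a - b)))
  f <- tempfile(fileext = ".png")
  render_difference_map(difference_map(a, b), f)
  expect_true(file.exists(f))
  arr <- png::readPNG(f)
  expect_equal(dim(arr)[1:2], c(8, 8))
})
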