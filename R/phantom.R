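#' Parameters of the synthetic anatomy and CBCT degradation model
#'
#' A phantom specification fully determines, together with an integer seed, a
#' CT-like phantom (elliptical body of soft tissue containing randomly placed
#' elliptical structures drawn from HU-like intensity classes) and its
#' CBCT-like degraded counterpart (blur, low-frequency cupping, streaks,
#' noise, and — for training images only — a small affine misalignment).
#'
#' Degradation magnitudes are free parameters of the simulation; the defaults
#' are chosen to resemble the artifact burden of clinical cone-beam CT
#' (shading on the order of 100 HU, noise of a few tens of HU, a handful of
#' reconstruction streaks) rather than calibrated to any particular scanner.
#'
#' @param image_size pixels per side (square), at least 32.
#' @param n_structures number of internal ellipses per phantom.
#' @param intensity_classes data.frame with columns `label`, `mean`, `spread`
#'   (HU-like). Means must be strictly increasing and must cover an air class
#'   near -1000, a soft-tissue class in 0..100, and a bone class in 300..1000.
#' @param cupping_amplitude depth of the radial cupping/shading bowl, HU-like.
#' @param n_streaks number of straight-line streak artifacts.
#' @param streak_amplitude maximal |streak| intensity, HU-like.
#' @param noise_sigma standard deviation of additive Gaussian noise, HU-like.
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @param misalign_max_shift maximal |translation| applied to training CBCT
#'   images, pixels.
#' @param misalign_max_rot maximal |rotation| applied to training CBCT images,
#'   degrees.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         n_structures = 6L,
                         intensity_classes = default_intensity_classes(),
                         cupping_amplitude = 120,
                         n_streaks = 8L,
                         streak_amplitude = 80,
                         noise_sigma = 50,
                         blur_sigma = 0.8,
                         misalign_max_shift = 2,
                         misalign_max_rot = 1) {
  check_count <- function(x, name, min = 0) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
      stop(sprintf("invalid phantom spec: `%s` must be an integer >= %d", name, min),
           call. = FALSE)
    }
  }
  check_nonneg <- function(x, name) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0) {
      stop(sprintf("invalid phantom spec: `%s` must be a nonnegative number", name),
           call. = FALSE)
    }
  }
  check_count(image_size, "image_size", min = 32)
  check_count(n_structures, "n_structures", min = 0)
  check_count(n_streaks, "n_streaks", min = 0)
  for (nm in c("cupping_amplitude", "streak_amplitude", "noise_sigma",
               "blur_sigma", "misalign_max_shift", "misalign_max_rot")) {
    check_nonneg(get(nm), nm)
  }
  ic <- intensity_classes
  if (!is.data.frame(ic) || !all(c("label", "mean", "spread") %in% names(ic))) {
    stop("invalid phantom spec: `intensity_classes` needs columns label, mean, spread",
         call. = FALSE)
  }
  if (nrow(ic) < 3 || any(diff(ic$mean) <= 0)) {
    stop("invalid phantom spec: `intensity_classes` means must be strictly increasing (air < soft tissue < bone)",
         call. = FALSE)
  }
  if (any(ic$spread < 0)) {
    stop("invalid phantom spec: `intensity_classes` spreads must be nonnegative",
         call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size),
                 n_structures = as.integer(n_structures),
                 intensity_classes = ic,
                 cupping_amplitude = cupping_amplitude,
                 n_streaks = as.integer(n_streaks),
                 streak_amplitude = streak_amplitude,
                 noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma,
                 misalign_max_shift = misalign_max_shift,
                 misalign_max_rot = misalign_max_rot),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_intensity_classes <- function() {
  data.frame(label = c("air", "soft_tissue", "bone"),
             mean = c(-1000, 40, 700),
             spread = c(0, 30, 150))
}

# Pixel-center coordinate grids (1-based, matching matrix indices).
coord_grids <- function(size) {
  list(row = matrix(rep(seq_len(size), size), size, size),
       col = matrix(rep(seq_len(size), each = size), size, size))
}

ellipse_mask <- function(size, cx, cy, a, b, theta, grids = coord_grids(size)) {
  dx <- grids$col - cx
  dy <- grids$row - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate a CT-like phantom
#'
#' Draws a piecewise-constant HU-like phantom: air background, an elliptical
#' soft-tissue body, and `n_structures` internal ellipses whose intensities
#' are drawn from the spec's intensity classes. Randomness is consumed in a
#' fixed, documented order (body geometry; then per structure: class, centre,
#' semi-axes, orientation, intensity) so that the mapping from `(spec, seed)`
#' to pixels is stable.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the output is a pure function of `(spec, seed)`.
#' @return A `domain_image` (domain `"B_ct"`, scale `"hu_like"`) carrying the
#'   generation parameters in attributes `body_ellipse` and `structures`.
#' @export
generate_ct_phantom <- function(spec, seed) {
  if (!inherits(spec, "phantom_spec")) {
    stop("invalid phantom spec: `spec` must be a phantom_spec", call. = FALSE)
  }
  s <- spec$image_size
  ic <- spec$intensity_classes
  air <- ic$mean[1]
  soft <- ic$mean[which(ic$label == "soft_tissue")[1]]
  if (is.na(soft)) soft <- ic$mean[2]
  local_seed(seed, {
    grids <- coord_grids(s)
    # 1. body ellipse geometry (5 draws)
    cx <- (s + 1) / 2 + runif(1, -0.03, 0.03) * s
    cy <- (s + 1) / 2 + runif(1, -0.03, 0.03) * s
    a <- runif(1, 0.32, 0.42) * s
    b <- runif(1, 0.30, 0.40) * s
    theta <- runif(1, 0, pi)
    img <- matrix(air, s, s)
    body <- ellipse_mask(s, cx, cy, a, b, theta, grids)
    img[body] <- soft
    # 2. internal structures, drawn in order (later ellipses overwrite)
    structures <- vector("list", spec$n_structures)
    for (i in seq_len(spec$n_structures)) {
      cls <- sample.int(nrow(ic), 1)
      # uniform position inside a shrunken copy of the body ellipse
      rr <- sqrt(runif(1)) * 0.75
      ang <- runif(1, 0, 2 * pi)
      ex <- cx + rr * (a * cos(ang) * cos(theta) - b * sin(ang) * sin(theta))
      ey <- cy + rr * (a * cos(ang) * sin(theta) + b * sin(ang) * cos(theta))
      ea <- runif(1, 0.05, 0.16) * s
      eb <- runif(1, 0.05, 0.16) * s
      eth <- runif(1, 0, pi)
      value <- ic$mean[cls] + runif(1, -1, 1) * ic$spread[cls]
      m <- ellipse_mask(s, ex, ey, ea, eb, eth, grids) & body
      img[m] <- value
      structures[[i]] <- list(class = ic$label[cls], cx = ex, cy = ey,
                              a = ea, b = eb, theta = eth, value = value)
    }
    out <- domain_image(img, domain = "B_ct", scale = "hu_like")
    attr(out, "body_ellipse") <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
    attr(out, "structures") <- structures
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Compute a body-contour mask by thresholding
#'
#' Stands in for the clinician-drawn body contour: pixels above
#' `air_threshold` are candidate anatomy; the largest connected component is
#' kept and its internal holes (air cavities) are filled, which is how a
#' clinical body outline is drawn.
#'
#' @param ct a `domain_image` on the hu_like scale.
#' @param air_threshold HU-like threshold separating air from anatomy.
#' @return Binary (0/1) integer matrix of the same size.
#' @export
generate_body_mask <- function(ct, air_threshold = -500) {
  assert_hu(ct, "ct")
  fg <- ct$pixels > air_threshold
  if (!any(fg)) {
    stop("empty mask: no pixels above the air threshold", call. = FALSE)
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(tab)
  mask <- matrix(0L, nrow(fg), ncol(fg))
  mask[lab == keep] <- 1L
  filled <- EBImage::fillHull(mask)
  matrix(as.integer(filled > 0), nrow(fg), ncol(fg))
}

# Gaussian blur with edge replication, used by the degradation model.
gaussian_kernel <- function(sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  half <- (k - 1L) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kern <- gaussian_kernel(sigma)
  half <- (nrow(kern) - 1L) / 2
  ri <- c(rep(1L, half), seq_len(nrow(mat)), rep(nrow(mat), half))
  ci <- c(rep(1L, half), seq_len(ncol(mat)), rep(ncol(mat), half))
  padded <- mat[ri, ci]
  x <- array(padded, c(dim(padded), 1L, 1L))
  w <- array(kern, c(dim(kern), 1L, 1L))
  conv2d_value(x, w, NULL, 1L, 0L)[, , 1, 1]
}

# Resample with a small rigid transform (rotation about the centre plus a
# translation), bilinear interpolation, `fill` outside the source support.
affine_resample <- function(mat, shift_x = 0, shift_y = 0, rot_deg = 0, fill = -1000) {
  s <- dim(mat)
  grids <- coord_grids(s[1])
  if (s[1] != s[2]) grids <- list(row = row(mat), col = col(mat))
  th <- rot_deg * pi / 180
  cx <- (s[2] + 1) / 2
  cy <- (s[1] + 1) / 2
  dx <- grids$col - cx
  dy <- grids$row - cy
  # inverse map: destination pixel -> source location
  sx <- cx + cos(th) * dx + sin(th) * dy - shift_x
  sy <- cy - sin(th) * dx + cos(th) * dy - shift_y
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get_px <- function(yy, xx) {
    ok <- xx >= 1 & xx <= s[2] & yy >= 1 & yy <= s[1]
    out <- matrix(fill, s[1], s[2])
    out[ok] <- mat[cbind(yy[ok], xx[ok])]
    out
  }
  v00 <- get_px(y0, x0); v10 <- get_px(y0 + 1, x0)
  v01 <- get_px(y0, x0 + 1); v11 <- get_px(y0 + 1, x0 + 1)
  (v00 * (1 - fy) + v10 * fy) * (1 - fx) + (v01 * (1 - fy) + v11 * fy) * fx
}

# The quadratic radial cupping bowl: 0 at the image corners, -amplitude at
# the centre (CBCT shading darkens the centre of the field of view).
cupping_field <- function(size, amplitude) {
  grids <- coord_grids(size)
  cx <- (size + 1) / 2
  r2 <- (grids$col - cx)^2 + (grids$row - cx)^2
  r2max <- 2 * (1 - cx)^2
  -amplitude * (1 - r2 / r2max)
}

#' Degrade a CT phantom into a CBCT-like image
#'
#' Applies, in order: Gaussian blur (`blur_sigma`), the radial cupping field
#' (`cupping_amplitude`, darker at the centre, zero at the corners),
#' `n_streaks` full-width one-pixel straight streaks with intensities drawn
#' uniformly from `[-streak_amplitude, streak_amplitude]`, and zero-mean
#' Gaussian noise (`noise_sigma`). Randomness is consumed in the order:
#' streak parameters (angle, centre, intensity per streak), then the noise
#' field. The output is a pure function of `(ct, spec, seed)`.
#'
#' @param ct a `domain_image` on the hu_like scale.
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the stochastic degradations.
#' @return A `domain_image` in domain `"A_cbct"`, hu_like scale, same size.
#' @export
degrade_to_cbct <- function(ct, spec, seed) {
  assert_hu(ct, "ct")
  if (!inherits(spec, "phantom_spec")) {
    stop("invalid phantom spec: `spec` must be a phantom_spec", call. = FALSE)
  }
  px <- ct$pixels
  s <- dim(px)
  local_seed(seed, {
    out <- gaussian_blur(px, spec$blur_sigma)
    if (spec$cupping_amplitude > 0) {
      stopifnot(s[1] == s[2])
      out <- out + cupping_field(s[1], spec$cupping_amplitude)
    }
    if (spec$n_streaks > 0 && spec$streak_amplitude > 0) {
      grids <- coord_grids(s[1])
      for (i in seq_len(spec$n_streaks)) {
        ang <- runif(1, 0, pi)
        pxc <- runif(1, 0.2, 0.8) * s[2]
        pyc <- runif(1, 0.2, 0.8) * s[1]
        amp <- runif(1, -spec$streak_amplitude, spec$streak_amplitude)
        d <- abs(-sin(ang) * (grids$col - pxc) + cos(ang) * (grids$row - pyc))
        out[d < 0.5] <- out[d < 0.5] + amp
      }
    } else if (spec$n_streaks > 0) {
      # keep the RNG stream aligned even when the amplitude is zero
      runif(4 * spec$n_streaks)
    }
    if (spec$noise_sigma > 0) {
      out <- out + matrix(rnorm(length(out), 0, spec$noise_sigma), s[1], s[2])
    }
    domain_image(out, domain = "A_cbct", scale = "hu_like")
  })
}

#' Assemble an unpaired training set plus aligned test pairs
#'
#' Training domain A (CBCT-like) and domain B (CT-like) images come from
#' disjoint phantom seeds and are shuffled independently, so they are
#' genuinely unpaired. Training CBCT images additionally receive a small
#' random rigid misalignment (bounded by the spec's `misalign_max_*`),
#' emulating setup differences between scans. Test pairs are built from
#' held-out seeds and are pixel-aligned: `(degraded, clean, body mask)`.
#'
#' @param spec a [phantom_spec()].
#' @param n_train_per_domain training images per domain (>= 1).
#' @param n_test aligned test pairs (>= 1; evaluation requires pairs).
#' @param seed integer; the bundle is a pure function of `(spec, seed, counts)`.
#' @return An object of class `dataset_bundle` with fields `train_A`,
#'   `train_B`, `test_pairs`, `seed`, `spec`.
#' @export
build_dataset <- function(spec, n_train_per_domain, n_test, seed) {
  if (!inherits(spec, "phantom_spec")) {
    stop("invalid phantom spec: `spec` must be a phantom_spec", call. = FALSE)
  }
  if (n_train_per_domain < 1) {
    stop("configuration error: `n_train_per_domain` must be >= 1", call. = FALSE)
  }
  if (n_test < 1) {
    stop("configuration error: `n_test` must be >= 1 (evaluation requires aligned pairs)",
         call. = FALSE)
  }
  local_seed(seed, {
    n_a <- n_train_per_domain
    ss <- sample.int(.Machine$integer.max - 1L, 3L * n_a + 2L * n_test)
    seed_a <- ss[seq_len(n_a)]
    seed_a_deg <- ss[n_a + seq_len(n_a)]
    seed_b <- ss[2L * n_a + seq_len(n_a)]
    seed_t <- ss[3L * n_a + seq_len(n_test)]
    seed_t_deg <- ss[3L * n_a + n_test + seq_len(n_test)]
    air <- spec$intensity_classes$mean[1]
    train_A <- lapply(seq_len(n_a), function(i) {
      ct <- generate_ct_phantom(spec, seed_a[i])
      cbct <- degrade_to_cbct(ct, spec, seed_a_deg[i])
      if (spec$misalign_max_shift > 0 || spec$misalign_max_rot > 0) {
        shifts <- runif(2, -spec$misalign_max_shift, spec$misalign_max_shift)
        rot <- runif(1, -spec$misalign_max_rot, spec$misalign_max_rot)
        cbct <- domain_image(
          affine_resample(cbct$pixels, shifts[1], shifts[2], rot, fill = air),
          domain = "A_cbct", scale = "hu_like")
      }
      cbct
    })
    train_B <- lapply(seed_b, function(sd) generate_ct_phantom(spec, sd))
    test_pairs <- lapply(seq_len(n_test), function(i) {
      ct <- generate_ct_phantom(spec, seed_t[i])
      cbct <- degrade_to_cbct(ct, spec, seed_t_deg[i])
      mask <- generate_body_mask(ct)
      list(A = cbct, B = ct, mask = mask)
    })
    train_A <- train_A[sample.int(n_a)]
    train_B <- train_B[sample.int(n_a)]
    structure(list(train_A = train_A, train_B = train_B,
                   test_pairs = test_pairs, seed = as.integer(seed),
                   spec = spec),
              class = "dataset_bundle")
  })
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d train A (CBCT-like), %d train B (CT-like), %d aligned test pairs, seed %d\n",
              length(x$train_A), length(x$train_B), length(x$test_pairs), x$seed))
  invisible(x)
}
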