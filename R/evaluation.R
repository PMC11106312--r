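#' Mean absolute error between aligned slice sets
#'
#' Mean over slices and pixels of `|ct - sct|`, optionally restricted to a
#' body mask per slice.
#'
#' @param ct_slices,sct_slices matrices, `domain_image`s, or lists thereof
#'   (equal counts and shapes).
#' @param masks optional binary mask or list of masks.
#' @return Nonnegative scalar in the units of the inputs.
#' @export
metric_mae <- function(ct_slices, sct_slices, masks = NULL) {
  xs <- as_slice_list(ct_slices)
  ys <- as_slice_list(sct_slices)
  if (length(xs) != length(ys)) stop("slice count mismatch", call. = FALSE)
  ms <- as_mask_list(masks, length(xs))
  total <- 0
  count <- 0
  for (i in seq_along(xs)) {
    if (!all(dim(xs[[i]]) == dim(ys[[i]]))) {
      stop("slice shape mismatch", call. = FALSE)
    }
    d <- abs(xs[[i]] - ys[[i]])
    if (!is.null(ms[[i]])) d <- d[ms[[i]] == 1]
    total <- total + sum(d)
    count <- count + length(d)
  }
  total / count
}

as_slice_list <- function(x) {
  if (is_domain_image(x)) return(list(x$pixels))
  if (is.matrix(x)) return(list(x))
  lapply(x, function(s) if (is_domain_image(s)) s$pixels else s)
}

as_mask_list <- function(masks, n) {
  if (is.null(masks)) return(vector("list", n))
  if (is.matrix(masks)) return(rep(list(masks), n))
  masks
}

#' Peak signal-to-noise ratio
#'
#' The standard convention is `10 * log10(MAX^2 / MSE)` in dB. The
#' `as_printed` convention, `20 * log10(MAX / MSE)`, divides by the MSE
#' rather than the RMSE; it is retained so both definitions are available,
#' but the standard form is the default. `MAX` defaults to the maximum pixel
#' of the synthetic image (`sct`), configurable via `max_value`. Identical
#' images have zero MSE; the result is then `Inf` carrying attribute
#' `identical = TRUE`.
#'
#' @param ct,sct matrices or `domain_image`s of equal shape.
#' @param convention `"standard"` or `"as_printed"`.
#' @param max_value dynamic-range maximum; default `max(sct)`.
#' @param mask optional binary mask restricting the MSE.
#' @return PSNR in dB.
#' @export
metric_psnr <- function(ct, sct, convention = c("standard", "as_printed"),
                        max_value = NULL, mask = NULL) {
  convention <- match.arg(convention)
  x <- if (is_domain_image(ct)) ct$pixels else ct
  y <- if (is_domain_image(sct)) sct$pixels else sct
  if (is.null(max_value)) max_value <- max(y)
  d <- (x - y)^2
  if (!is.null(mask)) d <- d[mask == 1]
  mse <- mean(d)
  if (mse == 0) {
    return(structure(Inf, identical = TRUE))
  }
  if (convention == "standard") {
    10 * log10(max_value^2 / mse)
  } else {
    20 * log10(max_value / mse)
  }
}

#' Structural similarity index
#'
#' Local SSIM computed in sliding Gaussian windows (default 11x11, sigma 1.5,
#' valid positions only) and averaged. `window = NULL` computes a single
#' global window (the plain closed form). Stability constants default to the
#' community convention `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` with `L` the
#' dynamic range (`data_range`).
#'
#' The SSIM formula uses the variances directly in its denominator
#' `(sigma_x^2 + sigma_y^2 + c2)`; here `sigma_x^2` denotes the variance of
#' `x` within the window and `sigma_xy` the covariance.
#'
#' @param x,y matrices or `domain_image`s of equal shape.
#' @param data_range dynamic range `L`; default 2 for normalized images,
#'   otherwise the observed joint range.
#' @param window_size odd window side in pixels, or `NULL` for global.
#' @param window_sigma Gaussian window standard deviation.
#' @param c1,c2 override the stability constants directly.
#' @return SSIM in `[-1, 1]`.
#' @export
metric_ssim <- function(x, y, data_range = NULL, window_size = 11L,
                        window_sigma = 1.5, c1 = NULL, c2 = NULL) {
  xs <- if (is_domain_image(x)) x$pixels else x
  ys <- if (is_domain_image(y)) y$pixels else y
  stopifnot(all(dim(xs) == dim(ys)))
  if (is.null(data_range)) {
    norm_in <- is_domain_image(x) && x$scale == "normalized"
    data_range <- if (norm_in) 2 else max(max(xs), max(ys)) - min(min(xs), min(ys))
    if (data_range == 0) data_range <- 1
  }
  if (is.null(c1)) c1 <- (0.01 * data_range)^2
  if (is.null(c2)) c2 <- (0.03 * data_range)^2
  if (is.null(window_size)) {
    mu_x <- mean(xs); mu_y <- mean(ys)
    var_x <- mean((xs - mu_x)^2); var_y <- mean((ys - mu_y)^2)
    cov_xy <- mean((xs - mu_x) * (ys - mu_y))
    return(((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
             ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2)))
  }
  if (window_size %% 2 != 1 || any(dim(xs) < window_size)) {
    stop("`window_size` must be odd and no larger than the image", call. = FALSE)
  }
  kern <- gaussian_window(window_size, window_sigma)
  filt <- function(m) {
    conv2d_value(array(m, c(dim(m), 1L, 1L)),
                 array(kern, c(dim(kern), 1L, 1L)), NULL, 1L, 0L)[, , 1, 1]
  }
  mu_x <- filt(xs); mu_y <- filt(ys)
  var_x <- filt(xs^2) - mu_x^2
  var_y <- filt(ys^2) - mu_y^2
  cov_xy <- filt(xs * ys) - mu_x * mu_y
  ssim_map <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  mean(ssim_map)
}

gaussian_window <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Evaluate a generator on aligned test pairs
#'
#' Each pair's A member (CBCT-like) is normalized, translated, mapped back to
#' HU-like units (when `scale = "hu"`), and compared with the B member (CT)
#' inside the pair's body mask: both images have the mask applied (outside
#' pixels read as air in both, so they contribute nothing), MAE and PSNR are
#' computed over masked pixels, SSIM over the masked images.
#'
#' @param test_pairs list of `list(A, B, mask)` from [build_dataset()], with
#'   hu_like members.
#' @param translator a `cbct_generator`, a `cyclegan_model` (its `gen_ab` is
#'   used), or a function mapping a normalized `domain_image` to one.
#' @param window a [norm_window()] for normalization/denormalization.
#' @param scale `"hu"` (metrics in HU-like units) or `"normalized"`.
#' @param masked compute metrics inside the body mask (default) or globally.
#' @param psnr_convention,psnr_max passed to [metric_psnr()].
#' @return An object of class `metric_report`: aggregate `mae`, `psnr`,
#'   `ssim`, `n_slices`, and a `per_slice` data.frame. Aggregates are means
#'   of the per-slice values.
#' @export
evaluate_pairs <- function(test_pairs, translator, window = norm_window(),
                           scale = c("hu", "normalized"), masked = TRUE,
                           psnr_convention = "standard", psnr_max = NULL) {
  scale <- match.arg(scale)
  fn <- translator_fn(translator)
  # one batched generator pass when every pair shares the same dimensions
  sct_batch <- NULL
  if (inherits(translator, c("cbct_generator", "cyclegan_model"))) {
    dims <- vapply(test_pairs, function(p) dim(p$A$pixels), numeric(2))
    if (ncol(unique(t(dims))) == 1) {
      gen <- if (inherits(translator, "cyclegan_model")) translator$gen_ab else translator
      arr <- array(unlist(lapply(test_pairs, function(p) {
        normalize_image(p$A, window)$pixels
      })), c(dims[1, 1], dims[2, 1], 1L, length(test_pairs)))
      sct_batch <- translate_batch(gen, arr)
    }
  }
  rows <- lapply(seq_along(test_pairs), function(i) {
    pair <- test_pairs[[i]]
    stopifnot(all(dim(pair$A$pixels) == dim(pair$B$pixels)))
    mask <- if (masked) pair$mask else NULL
    sct_n <- if (!is.null(sct_batch)) {
      domain_image(matrix(sct_batch[, , 1, i], dim(pair$A$pixels)[1]),
                   domain = "B_ct", scale = "normalized")
    } else {
      fn(normalize_image(pair$A, window))
    }
    if (scale == "hu") {
      sct <- denormalize_image(sct_n, window)
      ct <- pair$B
      rng <- window$hu_max - window$hu_min
    } else {
      sct <- sct_n
      ct <- normalize_image(pair$B, window)
      rng <- 2
    }
    if (!is.null(mask)) {
      sct <- apply_mask(sct, mask)
      ct <- apply_mask(ct, mask)
    }
    data.frame(
      slice = i,
      mae = metric_mae(ct, sct, masks = mask),
      psnr = as.numeric(metric_psnr(ct, sct, psnr_convention,
                                    max_value = psnr_max, mask = mask)),
      ssim = metric_ssim(ct, sct, data_range = rng))
  })
  per_slice <- do.call(rbind, rows)
  structure(list(mae = mean(per_slice$mae), psnr = mean(per_slice$psnr),
                 ssim = mean(per_slice$ssim), n_slices = nrow(per_slice),
                 per_slice = per_slice, scale = scale, masked = masked),
            class = "metric_report")
}

translator_fn <- function(translator) {
  if (inherits(translator, "cyclegan_model")) translator <- translator$gen_ab
  if (inherits(translator, "cbct_generator")) {
    gen <- translator
    function(img) translate(img, gen)
  } else if (is.function(translator)) {
    translator
  } else {
    stop("`translator` must be a generator, model, or function", call. = FALSE)
  }
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d (%s, %s)\n  MAE  %.4f\n  PSNR %.4f dB\n  SSIM %.4f\n",
              x$n_slices, x$scale, if (x$masked) "masked" else "unmasked",
              x$mae, x$psnr, x$ssim))
  invisible(x)
}

#' Histogram of HU-like values over a slice set
#'
#' Counts per bin over the given HU range, restricted to body masks when
#' provided (matching how intensity distributions of anatomy are compared).
#'
#' @param images matrix/`domain_image` or list thereof, hu_like scale.
#' @param masks optional mask or list of masks.
#' @param range HU range analysed (default -500..500).
#' @param bins number of equal-width bins.
#' @return data.frame with bin `lower`, `upper`, `mid`, `count`.
#' @export
hu_histogram <- function(images, masks = NULL, range = c(-500, 500),
                         bins = 50L) {
  xs <- as_slice_list(images)
  ms <- as_mask_list(masks, length(xs))
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  counts <- numeric(bins)
  for (i in seq_along(xs)) {
    v <- xs[[i]]
    if (!is.null(ms[[i]])) v <- v[ms[[i]] == 1]
    v <- v[v >= range[1] & v <= range[2]]
    h <- hist(v, breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }
  data.frame(lower = head(breaks, -1), upper = tail(breaks, -1),
             mid = (head(breaks, -1) + tail(breaks, -1)) / 2, count = counts)
}

#' Mean-intensity profiles along the image axes
#'
#' The mean intensity at each row index and each column index, averaged over
#' a slice set: the per-axis intensity distribution curves used to compare
#' synthetic and real CT.
#'
#' @param images matrix/`domain_image` or list thereof (equal sizes).
#' @return List with numeric vectors `row` and `col`, each of length equal to
#'   the image side.
#' @export
axis_profiles <- function(images) {
  xs <- as_slice_list(images)
  row_acc <- 0
  col_acc <- 0
  for (m in xs) {
    row_acc <- row_acc + rowMeans(m)
    col_acc <- col_acc + colMeans(m)
  }
  list(row = row_acc / length(xs), col = col_acc / length(xs))
}

#' Signed difference map between two images
#'
#' @param a,b matrices or `domain_image`s of equal shape.
#' @return List with `signed` (`a - b`) and `abs` (`|a - b|`) matrices.
#' @export
difference_map <- function(a, b) {
  am <- if (is_domain_image(a)) a$pixels else a
  bm <- if (is_domain_image(b)) b$pixels else b
  stopifnot(all(dim(am) == dim(bm)))
  d <- am - bm
  list(signed = d, abs = abs(d))
}

#' Render an absolute-difference map to a PNG
#'
#' Rainbow colour mapping with blue at minimal difference and red at maximal,
#' scaled to `max_abs` (default: the map's own maximum).
#'
#' @param dm output of [difference_map()] (or a matrix of |differences|).
#' @param path PNG destination.
#' @param max_abs colour-scale maximum.
#' @export
render_difference_map <- function(dm, path, max_abs = NULL) {
  m <- if (is.list(dm)) dm$abs else abs(dm)
  if (is.null(max_abs) || max_abs <= 0) max_abs <- max(m, 1e-12)
  v <- pmin(m / max_abs, 1)
  # hue 4/6 (blue) down to 0 (red)
  cols <- rainbow(256L, start = 0, end = 4 / 6)
  idx <- 256L - pmin(255L, as.integer(round(v * 255))) # blue = small
  rgbv <- col2rgb(cols[idx]) / 255
  arr <- array(0, c(nrow(m), ncol(m), 3L))
  arr[, , 1] <- matrix(rgbv[1, ], nrow(m), ncol(m))
  arr[, , 2] <- matrix(rgbv[2, ], nrow(m), ncol(m))
  arr[, , 3] <- matrix(rgbv[3, ], nrow(m), ncol(m))
  png::writePNG(arr, path)
  invisible(path)
}
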