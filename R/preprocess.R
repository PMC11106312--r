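#' Intensity normalization window
#'
#' The affine window mapping HU-like intensities to the `[-1, 1]` range the
#' networks operate on: `hu_min` maps to -1 and `hu_max` to +1. The default
#' (-1000, 1000) covers air through dense bone with headroom around the
#' -500..500 HU band where soft-tissue contrast lives.
#'
#' @param hu_min,hu_max window bounds, `hu_min < hu_max`.
#' @return An object of class `norm_window`.
#' @export
norm_window <- function(hu_min = -1000, hu_max = 1000) {
  if (!is.numeric(hu_min) || !is.numeric(hu_max) || hu_min >= hu_max) {
    stop("degenerate window: hu_min must be < hu_max", call. = FALSE)
  }
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "norm_window")
}

#' Multiply a body mask into an image
#'
#' Pixels outside the mask are set to the background value so that removed
#' regions read as air rather than 0 HU (which would be water-equivalent).
#' On the hu_like scale the background is `background` (default -1000); on
#' the normalized scale it is -1. Applying the same mask twice is a no-op.
#'
#' @param image a `domain_image`.
#' @param mask binary matrix of identical dimensions.
#' @param background override for the outside-mask value (hu_like scale only).
#' @return A `domain_image` of the same domain and scale.
#' @export
apply_mask <- function(image, mask, background = NULL) {
  if (!is_domain_image(image)) stop("`image` must be a domain_image", call. = FALSE)
  if (!all(dim(mask) == dim(image$pixels))) {
    stop("shape mismatch between image and mask", call. = FALSE)
  }
  bg <- if (image$scale == "hu_like") {
    if (is.null(background)) -1000 else background
  } else {
    -1
  }
  px <- image$pixels
  px[mask == 0] <- bg
  domain_image(px, domain = image$domain, scale = image$scale)
}

#' Normalize an HU-like image to [-1, 1]
#'
#' Affine map sending `window$hu_min` to -1 and `window$hu_max` to +1,
#' clipped to `[-1, 1]`.
#'
#' @param image a `domain_image` on the hu_like scale.
#' @param window a [norm_window()].
#' @return A `domain_image` on the normalized scale.
#' @export
normalize_image <- function(image, window = norm_window()) {
  assert_hu(image, "image")
  px <- 2 * (image$pixels - window$hu_min) / (window$hu_max - window$hu_min) - 1
  px <- pmin(pmax(px, -1), 1)
  domain_image(px, domain = image$domain, scale = "normalized")
}

#' Map a normalized image back to HU-like units
#'
#' Exact inverse of [normalize_image()] for intensities inside the window.
#'
#' @inheritParams normalize_image
#' @export
denormalize_image <- function(image, window = norm_window()) {
  if (!is_domain_image(image)) stop("`image` must be a domain_image", call. = FALSE)
  if (image$scale != "normalized") {
    stop("denormalize_image() expects a normalized image", call. = FALSE)
  }
  px <- (image$pixels + 1) / 2 * (window$hu_max - window$hu_min) + window$hu_min
  domain_image(px, domain = image$domain, scale = "hu_like")
}

#' Resize an image with bilinear resampling
#'
#' Uses half-pixel-centre coordinate mapping, under which constant images
#' stay exactly constant and resizing to the same size is the identity.
#'
#' @param image a `domain_image`.
#' @param size target side length in pixels (>= 1; square output).
#' @export
resize_image <- function(image, size) {
  if (!is_domain_image(image)) stop("`image` must be a domain_image", call. = FALSE)
  size <- as.integer(size)
  if (size < 1) stop("`size` must be positive", call. = FALSE)
  x <- array(image$pixels, c(dim(image$pixels), 1L, 1L))
  y <- .resize_bilinear_cpp(x, size, size)[, , 1, 1, drop = TRUE]
  y <- matrix(y, size, size)
  if (image$scale == "normalized") y <- pmin(pmax(y, -1), 1)
  domain_image(y, domain = image$domain, scale = image$scale)
}
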