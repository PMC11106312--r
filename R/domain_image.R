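#' 2-D intensity image tagged with its domain and intensity scale
#'
#' The package's basic container: a numeric matrix of pixel intensities plus
#' two tags — which translation domain the image belongs to (`"A_cbct"` for
#' cone-beam CT, `"B_ct"` for fan-beam CT) and which intensity convention its
#' values follow (`"hu_like"`, approximately Hounsfield units, or
#' `"normalized"`, every pixel in \eqn{[-1, 1]} as the networks expect).
#'
#' @param pixels numeric matrix (rows = image rows, columns = image columns).
#' @param domain `"A_cbct"` or `"B_ct"`.
#' @param scale `"hu_like"` or `"normalized"`.
#' @return An object of class `domain_image`.
#' @export
domain_image <- function(pixels, domain = c("A_cbct", "B_ct"),
                         scale = c("hu_like", "normalized")) {
  domain <- match.arg(domain)
  scale <- match.arg(scale)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` contains missing values", call. = FALSE)
  if (scale == "normalized" && (min(pixels) < -1 - 1e-9 || max(pixels) > 1 + 1e-9)) {
    stop("normalized images must have every pixel in [-1, 1]", call. = FALSE)
  }
  structure(list(pixels = pixels, domain = domain, scale = scale),
            class = "domain_image")
}

is_domain_image <- function(x) inherits(x, "domain_image")

#' @export
print.domain_image <- function(x, ...) {
  cat(sprintf("<domain_image> %dx%d  domain=%s  scale=%s  range=[%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$domain, x$scale,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.domain_image <- function(x) dim(x$pixels)

assert_hu <- function(image, what = "image") {
  if (!is_domain_image(image)) stop(what, " must be a domain_image", call. = FALSE)
  if (image$scale != "hu_like") {
    stop(what, " must be on the hu_like scale", call. = FALSE)
  }
  invisible(image)
}

assert_normalized <- function(image, what = "image") {
  if (!is_domain_image(image)) stop(what, " must be a domain_image", call. = FALSE)
  if (image$scale != "normalized") {
    stop(what, " must be on the normalized scale", call. = FALSE)
  }
  invisible(image)
}

other_domain <- function(domain) {
  if (domain == "A_cbct") "B_ct" else "A_cbct"
}

# Run code under a private, seeded RNG stream without disturbing the caller's.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
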