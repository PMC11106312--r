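# Image I/O. The native on-disk format for HU-like images is 16-bit TIFF
# with an affine-packing JSON sidecar (`<file>.json` holding hu_min/hu_max):
# stored_value = (hu - hu_min) / (hu_max - hu_min) * 65535. PNG is supported
# for reading (8- or 16-bit, sidecar required) and for 8-bit writing; NIfTI
# stores HU-like values directly (no sidecar). Masks are 8-bit PNG.

packing_sidecar_path <- function(path) paste0(path, ".json")

write_packing_sidecar <- function(path, hu_min, hu_max, domain) {
  jsonlite::write_json(list(hu_min = hu_min, hu_max = hu_max, domain = domain,
                            packing = "affine_uint"),
                       packing_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         tif = , tiff = "tiff",
         png = "png",
         nii = "nifti",
         dcm = "dicom_series",
         stop("unrecognized image extension: ", ext, call. = FALSE))
}

#' Write a domain image to disk
#'
#' TIFF (16-bit, exact to 1/65535 of the packing window) and PNG (8-bit) get
#' a JSON sidecar recording the affine packing constants; NIfTI stores the
#' HU-like values directly.
#'
#' @param image a `domain_image` on the hu_like scale.
#' @param path destination; format chosen by extension (`.tif`/`.tiff`,
#'   `.png`, `.nii`/`.nii.gz`).
#' @param hu_min,hu_max packing window (values clipped to it); by default the
#'   image's own range, recorded in the sidecar.
#' @export
write_domain_image <- function(image, path, hu_min = NULL, hu_max = NULL) {
  assert_hu(image, "image")
  if (is.null(hu_min)) hu_min <- floor(min(image$pixels))
  if (is.null(hu_max)) hu_max <- max(ceiling(max(image$pixels)), hu_min + 1)
  fmt <- file_format(path)
  if (fmt == "nifti") {
    RNifti::writeNifti(RNifti::asNifti(image$pixels), path)
    return(invisible(path))
  }
  v <- (image$pixels - hu_min) / (hu_max - hu_min)
  v <- pmin(pmax(v, 0), 1)
  if (fmt == "tiff") {
    v <- round(v * 65535) / 65535
    tiff::writeTIFF(v, path, bits.per.sample = 16L)
  } else if (fmt == "png") {
    png::writePNG(v, path)
  } else {
    stop("writing format `", fmt, "` is not supported", call. = FALSE)
  }
  write_packing_sidecar(path, hu_min, hu_max, image$domain)
  invisible(path)
}

#' Read a domain image from disk
#'
#' @param path source file. TIFF/PNG require the packing sidecar written by
#'   [write_domain_image()]; reading a bare 8/16-bit PNG without one is an
#'   error rather than a silent rescale. DICOM series are not supported.
#' @param domain override the domain tag (default: sidecar value, else
#'   `"B_ct"`).
#' @param slice for NIfTI volumes: axial slice index (first array index).
#' @return A `domain_image` on the hu_like scale.
#' @export
read_domain_image <- function(path, domain = NULL, slice = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- file_format(path)
  if (fmt == "dicom_series") {
    stop("unsupported format: DICOM reading is not available; convert to NIfTI",
         call. = FALSE)
  }
  if (fmt == "nifti") {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    px <- if (length(dim(arr)) == 3L) {
      if (is.null(slice)) {
        stop("NIfTI volume: supply `slice` (axial = first index)", call. = FALSE)
      }
      matrix(arr[slice, , ], dim(arr)[2], dim(arr)[3])
    } else {
      matrix(arr, dim(arr)[1], dim(arr)[2])
    }
    if (is.null(domain)) domain <- "B_ct"
    return(domain_image(px, domain = domain, scale = "hu_like"))
  }
  sc_path <- packing_sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop("missing packing sidecar for ", path,
         ": cannot map stored intensities to HU-like values", call. = FALSE)
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  v <- if (fmt == "tiff") tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  px <- v * (sc$hu_max - sc$hu_min) + sc$hu_min
  if (is.null(domain)) domain <- if (!is.null(sc$domain)) sc$domain else "B_ct"
  domain_image(px, domain = domain, scale = "hu_like")
}

#' Write or read a binary mask as 8-bit PNG
#'
#' @param mask binary 0/1 matrix.
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  matrix(as.integer(v > 0.5), nrow(v), ncol(v))
}

#' Write a dataset bundle to a directory tree
#'
#' Layout: `trainA/`, `trainB/` (16-bit TIFF + sidecars), `test/` with
#' aligned `*_A`, `*_B` images and `*_mask.png`, plus `manifest.json`
#' recording the seed, counts, and phantom spec.
#'
#' @param bundle a [build_dataset()] bundle.
#' @param dir destination directory (created).
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  for (d in c("trainA", "trainB", "test")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(bundle$train_A)) {
    write_domain_image(bundle$train_A[[i]],
                       file.path(dir, "trainA", sprintf("a_%04d.tif", i)))
  }
  for (i in seq_along(bundle$train_B)) {
    write_domain_image(bundle$train_B[[i]],
                       file.path(dir, "trainB", sprintf("b_%04d.tif", i)))
  }
  for (i in seq_along(bundle$test_pairs)) {
    p <- bundle$test_pairs[[i]]
    write_domain_image(p$A, file.path(dir, "test", sprintf("t_%04d_A.tif", i)))
    write_domain_image(p$B, file.path(dir, "test", sprintf("t_%04d_B.tif", i)))
    write_mask(p$mask, file.path(dir, "test", sprintf("t_%04d_mask.png", i)))
  }
  spec <- unclass(bundle$spec)
  spec$intensity_classes <- NULL
  jsonlite::write_json(
    list(seed = bundle$seed, n_train = length(bundle$train_A),
         n_test = length(bundle$test_pairs), spec = spec,
         intensity_classes = bundle$spec$intensity_classes),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle from a directory tree
#'
#' @param dir directory written by [write_dataset()].
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  read_dir <- function(sub, domain) {
    files <- sort(list.files(file.path(dir, sub), pattern = "\\.tif$",
                             full.names = TRUE))
    lapply(files, read_domain_image, domain = domain)
  }
  train_A <- read_dir("trainA", "A_cbct")
  train_B <- read_dir("trainB", "B_ct")
  n_test <- man$n_test
  test_pairs <- lapply(seq_len(n_test), function(i) {
    list(A = read_domain_image(file.path(dir, "test", sprintf("t_%04d_A.tif", i)),
                               domain = "A_cbct"),
         B = read_domain_image(file.path(dir, "test", sprintf("t_%04d_B.tif", i)),
                               domain = "B_ct"),
         mask = read_mask(file.path(dir, "test", sprintf("t_%04d_mask.png", i))))
  })
  spec_args <- man$spec
  spec <- phantom_spec(image_size = spec_args$image_size,
                       n_structures = spec_args$n_structures,
                       intensity_classes = as.data.frame(man$intensity_classes),
                       cupping_amplitude = spec_args$cupping_amplitude,
                       n_streaks = spec_args$n_streaks,
                       streak_amplitude = spec_args$streak_amplitude,
                       noise_sigma = spec_args$noise_sigma,
                       blur_sigma = spec_args$blur_sigma,
                       misalign_max_shift = spec_args$misalign_max_shift,
                       misalign_max_rot = spec_args$misalign_max_rot)
  structure(list(train_A = train_A, train_B = train_B,
                 test_pairs = test_pairs, seed = man$seed, spec = spec),
            class = "dataset_bundle")
}
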