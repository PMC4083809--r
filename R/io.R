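#' Load a grayscale image
#'
#' Reads PNG or TIFF (8/16-bit integer or float) and returns a numeric
#' matrix in `[0, 1]`. Integer images are scaled by the dtype maximum (the
#' readers do this natively); float images already in `[0, 1]` are kept
#' as-is, others are min-max rescaled with a warning. RGB(A) input is
#' converted to luminance (Rec. 709 weights) with a warning. A constant
#' image triggers a warning, not an error.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix, values in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    warning("RGB input converted to luminance", call. = FALSE)
    nch <- dim(img)[3]
    img <- if (nch >= 3) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img <- as.matrix(img)
  if (!all(is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("float image outside [0,1]; min-max rescaled", call. = FALSE)
    img <- (img - rng[1]) / (rng[2] - rng[1])
  }
  if (stats::sd(img) == 0) {
    warning("image has zero variance", call. = FALSE)
  }
  img
}

#' Save a float image as 32-bit TIFF
#'
#' Values must already lie in `[0, 1]`: the TIFF writer does not define
#' storage outside that range. Level-set fields are saved through
#' [save_levelset_tiff()], which normalizes and reports the affine range.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output `.tif`/`.tiff` path.
#' @return `path`, invisibly.
#' @export
save_image_tiff <- function(img, path) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (min(img) < 0 || max(img) > 1) {
    stop("save_image_tiff requires values in [0, 1]; ",
         "use save_levelset_tiff for unbounded fields", call. = FALSE)
  }
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Save an unbounded field as a normalized float TIFF
#'
#' Affinely maps the field onto `[0, 1]` for storage and returns the
#' original range so the field can be reconstructed
#' (`value = stored * (max - min) + min`).
#'
#' @param phi Numeric matrix (any finite values).
#' @param path Output `.tif`/`.tiff` path.
#' @return Numeric `c(min, max)` of the original field, invisibly.
#' @export
save_levelset_tiff <- function(phi, path) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  rng <- range(phi)
  scaled <- if (rng[2] > rng[1]) (phi - rng[1]) / (rng[2] - rng[1]) else phi * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(rng)
}

#' Save a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Load a binary mask from a PNG
#'
#' Pixels above half intensity are foreground.
#'
#' @param path Input `.png` path.
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  img > 0.5
}
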