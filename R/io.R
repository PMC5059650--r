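#' Read a dermoscopic image
#'
#' Loads a PNG, JPEG or TIFF raster (8- or 16-bit) and returns an
#' H x W x 3 numeric array with values scaled to \[0, 1\], row-major
#' with the origin at the top-left. Grayscale inputs are replicated to
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to an existing PNG/JPEG/TIFF file.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @examples
#' tf <- tempfile(fileext = ".png")
#' save_mask(matrix(c(TRUE, FALSE), 8, 8), tf)
#' img <- load_image(tf)
#' dim(img)
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_derm("file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_derm("cannot read image '", path,
                                                "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)
  ## EBImage stores (x, y[, channel]); transpose to (row, col).
  if (length(dim(a)) == 2L) {
    a <- t(a)
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else {
    a <- aperm(a, c(2L, 1L, 3L))
    if (dim(a)[3] == 2L) a <- a[, , 1L, drop = FALSE]        # gray + alpha
    if (dim(a)[3] == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
    if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]       # drop alpha
  }
  a <- clip01(a)
  if (dim(a)[1] < 8L || dim(a)[2] < 8L)
    stop_derm("image '", path, "' is smaller than 8 x 8 pixels")
  assert_image(a, "loaded image")
  a
}

#' Extract the CIELAB luminance channel
#'
#' Converts an sRGB image (D65/2° white point) to CIELAB and returns
#' L* divided by 100, so the luminance map lies in \[0, 1\]. All
#' enhancement and segmentation stages operate on this map.
#'
#' @param img H x W x 3 sRGB array in \[0, 1\].
#' @return H x W numeric matrix in \[0, 1\].
#' @export
extract_luminance <- function(img) {
  assert_image(img)
  d <- dim(img)
  rgb <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
               as.numeric(img[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  matrix(clip01(lab[, 1] / 100), d[1], d[2])
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (`TRUE`) is written as 255, background as 0, in a
#' single-channel 8-bit PNG; `load_mask()` inverts the encoding.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
save_mask <- function(mask, path) {
  assert_mask(mask)
  tryCatch(EBImage::writeImage(EBImage::Image(t(mask) * 1), path,
                               type = "png", bits.per.sample = 8L),
           error = function(e) stop_derm("cannot write mask to '", path,
                                         "': ", conditionMessage(e)))
  invisible(NULL)
}

#' @rdname save_mask
#' @return `load_mask()` returns a logical matrix (pixels > 127/255 are
#'   foreground).
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  img[, , 1] > 0.5
}

#' Write a \[0, 1\] image or map as PNG
#'
#' Single-channel matrices are written as 16-bit grayscale PNG (used for
#' debug dumps of response/luminance maps, min-max scaled when
#' `rescale = TRUE`); H x W x 3 arrays as 8-bit RGB PNG.
#'
#' @param x matrix or H x W x 3 array in \[0, 1\].
#' @param path output path.
#' @param rescale min-max scale a matrix before writing (default FALSE).
#' @export
save_image <- function(x, path, rescale = FALSE) {
  if (is.matrix(x)) {
    if (rescale && diff(range(x)) > 0) x <- (x - min(x)) / diff(range(x))
    EBImage::writeImage(EBImage::Image(t(clip01(x))), path, type = "png",
                        bits.per.sample = 16L)
  } else {
    assert_image(x)
    EBImage::writeImage(EBImage::Image(aperm(x, c(2L, 1L, 3L)),
                                       colormode = "Color"),
                        path, type = "png", bits.per.sample = 8L)
  }
  invisible(NULL)
}
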