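## Shared low-level helpers: validation, Otsu thresholding, reflective
## 2-D convolution, Gaussian kernels.

stop_derm <- function(...) stop(..., call. = FALSE)

assert_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_derm(sprintf("`%s` must be an H x W x 3 array", arg))
  if (dim(img)[1] < 8L || dim(img)[2] < 8L)
    stop_derm(sprintf("`%s` must be at least 8 x 8 pixels", arg))
  if (!all(is.finite(img)) || min(img) < 0 || max(img) > 1)
    stop_derm(sprintf("`%s` must be finite and within [0, 1]", arg))
  invisible(img)
}

assert_lum <- function(L, arg = "L") {
  if (!is.matrix(L)) stop_derm(sprintf("`%s` must be a numeric matrix", arg))
  if (!all(is.finite(L)) || min(L) < 0 || max(L) > 1)
    stop_derm(sprintf("`%s` must be finite and within [0, 1]", arg))
  invisible(L)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_derm(sprintf("`%s` must be a logical matrix", arg))
  if (anyNA(mask)) stop_derm(sprintf("`%s` must not contain NA", arg))
  invisible(mask)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Otsu threshold of a numeric map
#'
#' Between-class-variance-maximizing threshold of the values in `x`,
#' computed on a 256-bin histogram over \code{range}. This is the
#' `thresh()` primitive used by the skin-background rule and by lesion
#' binarization. Constant input has no defined threshold and returns
#' `NA` with a warning.
#'
#' @param x numeric matrix or vector.
#' @param range numeric length-2, histogram support (default `c(0, 1)`).
#' @param levels number of histogram bins (default 256).
#' @return A single numeric threshold, or `NA_real_` for constant input.
#' @export
otsu_threshold <- function(x, range = c(0, 1), levels = 256L) {
  v <- as.numeric(x)
  if (!all(is.finite(v))) stop_derm("`x` must be finite")
  if (diff(range(v)) < .Machine$double.eps) {
    warning("constant input: Otsu threshold undefined", call. = FALSE)
    return(NA_real_)
  }
  EBImage::otsu(EBImage::Image(matrix(v, nrow = 1L)),
                range = range, levels = levels)
}

## Reflective ("symmetric") padding: mirrors including the edge row/col.
pad_reflect <- function(m, pad) {
  H <- nrow(m); W <- ncol(m)
  if (pad >= H || pad >= W)
    stop_derm("reflective pad must be smaller than the image")
  ri <- c(pad:1, 1:H, H:(H - pad + 1))
  ci <- c(pad:1, 1:W, W:(W - pad + 1))
  m[ri, ci, drop = FALSE]
}

## 2-D linear convolution (correlation with a symmetric-support kernel)
## with reflective border handling; kernel must have odd dimensions.
## Uses EBImage's FFT filter on a reflect-padded copy so only interior
## (reflection-consistent) values are returned.
conv2_reflect <- function(m, kernel) {
  kh <- (nrow(kernel) - 1L) / 2L
  kw <- (ncol(kernel) - 1L) / 2L
  stopifnot(kh == round(kh), kw == round(kw))
  pad <- max(kh, kw)
  p <- pad_reflect(m, pad)
  f <- EBImage::filter2(EBImage::Image(p), kernel, boundary = "circular")
  as.matrix(f)[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m)), drop = FALSE]
}

## Unit-sum isotropic Gaussian kernel truncated at `truncate` sigma.
gaussian_kernel <- function(sigma, truncate = 3) {
  r <- max(1L, ceiling(truncate * sigma))
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- exp(-d / (2 * sigma^2))
  k / sum(k)
}
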