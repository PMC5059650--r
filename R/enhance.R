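#' Contrast-enhancement parameters
#'
#' Constants of the illumination-equalization and adaptive contrast
#' stretch, all on the unit luminance scale. Defaults are the values
#' the method was designed with: reference luminance `l_ref = 0.59`,
#' skin-intensity ceiling `k_skin = 0.75`, percentile window 1-99,
#' `b_bits = 4` (16-bin histogram for the cut-off), cut-off scaling
#' `scale_p = 0.88` and sigmoid `gain = 10`.
#'
#' @param l_ref reference luminance after equalization.
#' @param k_skin ceiling of the percentile-normalized luminance.
#' @param pct_lo,pct_hi lower/upper percentiles of the normalization
#'   window (in percent).
#' @param b_bits histogram quantization bits for the adaptive cut-off.
#' @param scale_p scaling applied to the modal bin centre to obtain the
#'   sigmoid cut-off, in (0, 1].
#' @param gain sigmoid gain.
#' @return An object of class `contrast_params`.
#' @export
contrast_params <- function(l_ref = 0.59, k_skin = 0.75, pct_lo = 1,
                            pct_hi = 99, b_bits = 4L, scale_p = 0.88,
                            gain = 10) {
  if (scale_p <= 0 || scale_p > 1) stop_derm("`scale_p` must be in (0, 1]")
  if (pct_lo >= pct_hi) stop_derm("`pct_lo` must be below `pct_hi`")
  if (b_bits < 1L || b_bits > 12L) stop_derm("`b_bits` must be in 1..12")
  structure(list(l_ref = l_ref, k_skin = k_skin, pct_lo = pct_lo,
                 pct_hi = pct_hi, b_bits = as.integer(b_bits),
                 scale_p = scale_p, gain = gain),
            class = "contrast_params")
}

#' @export
print.contrast_params <- function(x, ...) {
  cat("Contrast parameters: l_ref =", x$l_ref, " k_skin =", x$k_skin,
      " percentiles =", x$pct_lo, "-", x$pct_hi, "\n  b_bits =", x$b_bits,
      " scale_p =", x$scale_p, " gain =", x$gain, "\n")
  invisible(x)
}

#' Initial skin-background mask
#'
#' Marks as background (skin) every pixel whose luminance exceeds 1.2
#' times the Otsu threshold of the luminance map. Lesion pixels are
#' dark, so the bright side of an inflated Otsu split is a conservative
#' skin mask.
#'
#' @param L luminance matrix in \[0, 1\].
#' @return Logical matrix, `TRUE` = skin background.
#' @export
background_mask <- function(L) {
  assert_lum(L)
  t <- suppressWarnings(otsu_threshold(L))
  bg <- if (is.na(t)) matrix(FALSE, nrow(L), ncol(L)) else L > 1.2 * t
  if (!any(bg))
    stop_derm("no detectable skin background: no luminance above 1.2 * Otsu threshold")
  bg
}

## Normalized convolution: conv(signal * support, G) / conv(support, G),
## with fallback where the support weight vanishes.
normalized_convolution <- function(values, support, kernel, fallback) {
  num <- conv2_reflect(values * support, kernel)
  den <- conv2_reflect(support * 1, kernel)
  out <- matrix(fallback, nrow(values), ncol(values))
  ok <- den >= 1e-8
  out[ok] <- num[ok] / den[ok]
  out
}

#' Smoothed background luminance
#'
#' Normalized convolution of the luminance over the skin mask with a
#' unit-sum Gaussian kernel: `u_L = conv(L * bg, G) / conv(bg, G)`.
#' Where the local mask weight is below 1e-8 the global mean of `L`
#' over `bg` is substituted.
#'
#' @param L luminance matrix.
#' @param bg logical skin mask with at least one `TRUE` pixel.
#' @param sigma Gaussian standard deviation in pixels; default
#'   `min(dim(L)) / 8` (illumination varies at image scale).
#' @return Numeric matrix `u_L`.
#' @export
smoothed_background <- function(L, bg, sigma = min(dim(L)) / 8) {
  assert_lum(L); assert_mask(bg, "bg")
  if (!any(bg)) stop_derm("`bg` has no foreground pixel")
  normalized_convolution(L, bg, gaussian_kernel(sigma), mean(L[bg]))
}

#' Illumination estimate
#'
#' Restricts the smoothed background `u_L` to the good-fit mask
#' `G_fm = (|u_L - L| <= 0.05) & bg` and re-smooths it by normalized
#' convolution with the same Gaussian, giving the illumination field
#' `E_L`. `E_L` is clamped below at 0.05 so the subsequent division is
#' stable. If the good-fit mask is empty, `E_L` falls back to the
#' global mean of `u_L` over `bg` (with a warning).
#'
#' @param L luminance matrix.
#' @param uL smoothed background from [smoothed_background()].
#' @param bg logical skin mask.
#' @param sigma Gaussian standard deviation in pixels.
#' @return A list of class `illumination_model` with elements `bg`,
#'   `uL`, `Gfm`, `EL` and `sigma`.
#' @export
illumination_estimate <- function(L, uL, bg, sigma = min(dim(L)) / 8) {
  assert_lum(L); assert_mask(bg, "bg")
  gfm <- (abs(uL - L) <= 0.05) & bg
  if (!any(gfm)) {
    warning("good-fit mask empty: using global mean illumination", call. = FALSE)
    EL <- matrix(mean(uL[bg]), nrow(L), ncol(L))
  } else {
    EL <- normalized_convolution(uL, gfm, gaussian_kernel(sigma), mean(uL[bg]))
  }
  EL <- pmax(EL, 0.05)
  structure(list(bg = bg, uL = uL, Gfm = gfm, EL = EL, sigma = sigma),
            class = "illumination_model")
}

#' Equalize luminance against an illumination estimate
#'
#' `L_eq = l_ref * L / E_L`, clipped to \[0, 1\]. Where the
#' illumination estimate equals the true local illumination, skin
#' pixels land at the reference level `l_ref`.
#'
#' @param L luminance matrix.
#' @param EL illumination estimate, >= 0.05 everywhere.
#' @param l_ref reference luminance (default 0.59).
#' @return Equalized luminance matrix in \[0, 1\].
#' @export
equalize <- function(L, EL, l_ref = 0.59) {
  assert_lum(L)
  if (min(EL) < 0.05 - 1e-12) stop_derm("`EL` must be >= 0.05 everywhere")
  clip01(l_ref * L / EL)
}

#' Percentile contrast normalization
#'
#' Maps the 1st percentile of the equalized luminance to 0 and the
#' 99th percentile to `k_skin` (default 0.75), linearly in between and
#' clipping outside, so that skin pixels occupy a fixed upper band
#' below white.
#'
#' @param Leq equalized luminance matrix.
#' @param params a [contrast_params()] object.
#' @return Normalized luminance matrix in \[0, `k_skin`\].
#' @export
percentile_normalize <- function(Leq, params = contrast_params()) {
  assert_lum(Leq)
  p <- stats::quantile(Leq, c(params$pct_lo, params$pct_hi) / 100,
                       names = FALSE)
  if (p[2] - p[1] < 1e-6)
    stop_derm("degenerate contrast: percentile window narrower than 1e-6")
  params$k_skin * pmin(pmax((Leq - p[1]) / (p[2] - p[1]), 0), 1)
}

#' Adaptive sigmoid cut-off
#'
#' Builds a `2^b_bits`-bin histogram of the normalized luminance over
#' \[0, 1\] (the first-order difference of the cumulative histogram is
#' the histogram itself) and returns
#' `delta = scale_p * (i* + 0.5) / 2^b_bits`, the scaled centre of the
#' most populated bin. Ties are broken towards the brighter bin, since
#' skin is the dominant bright class.
#'
#' @param Lnorm normalized luminance matrix.
#' @param params a [contrast_params()] object.
#' @return The cut-off `delta`, a single numeric in (0, 1).
#' @export
adaptive_cutoff <- function(Lnorm, params = contrast_params()) {
  assert_lum(Lnorm)
  nb <- 2L^params$b_bits
  idx <- pmin(floor(as.numeric(Lnorm) * nb), nb - 1L)      # 0-based bins
  counts <- tabulate(idx + 1L, nbins = nb)
  istar <- max(which(counts == max(counts))) - 1L           # tie -> brighter
  params$scale_p * (istar + 0.5) / nb
}

#' Sigmoid contrast stretch
#'
#' Elementwise logistic map
#' `1 / (1 + exp(gain * (delta - L)))`: luminance above the cut-off
#' (skin) is pushed towards 1, below it (lesion) towards 0. Strictly
#' increasing in its input.
#'
#' @param Lnorm normalized luminance matrix.
#' @param delta cut-off in (0, 1), from [adaptive_cutoff()].
#' @param gain sigmoid gain (default 10).
#' @return Stretched luminance matrix in (0, 1).
#' @export
sigmoid_stretch <- function(Lnorm, delta, gain = 10) {
  if (delta <= 0 || delta >= 1) stop_derm("`delta` must be in (0, 1)")
  1 / (1 + exp(gain * (delta - Lnorm)))
}

#' Full luminance enhancement stage
#'
#' Composition of the enhancement pipeline on a hair-removed image:
#' luminance extraction, skin-background masking, Gaussian normalized
#' convolution, illumination estimation, equalization to `l_ref`,
#' percentile normalization and adaptive sigmoid stretch.
#'
#' @param img_inpainted H x W x 3 sRGB array (hair-removed).
#' @param params a [contrast_params()] object.
#' @param sigma Gaussian standard deviation for illumination
#'   estimation; default `min(H, W) / 8`.
#' @return A list with the stretched map `L` plus intermediates
#'   (`L_raw`, `illum`, `L_eq`, `L_norm`, `delta`).
#' @export
enhance <- function(img_inpainted, params = contrast_params(),
                    sigma = NULL) {
  assert_image(img_inpainted)
  L <- extract_luminance(img_inpainted)
  if (is.null(sigma)) sigma <- min(dim(L)) / 8
  bg <- background_mask(L)
  uL <- smoothed_background(L, bg, sigma)
  im <- illumination_estimate(L, uL, bg, sigma)
  Leq <- equalize(L, im$EL, params$l_ref)
  Ln <- percentile_normalize(Leq, params)
  delta <- adaptive_cutoff(Ln, params)
  Ls <- sigmoid_stretch(Ln, delta, params$gain)
  list(L = Ls, L_raw = L, illum = im, L_eq = Leq, L_norm = Ln, delta = delta)
}
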