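#' Binarize a Gabor response map into a hair mask
#'
#' Min-max normalizes the orientation-maximum response, thresholds it
#' with Otsu's method (256-bin histogram), dilates the result by a
#' small disk to cover hair halos, and discards connected components
#' smaller than `min_hair_px` pixels as noise. A constant response map
#' has no defined threshold and yields an empty mask with a warning.
#'
#' @param resp output of [orientation_max_response()], or a plain
#'   response matrix.
#' @param dilation_radius_px disk radius for post-dilation (default 1).
#' @param min_hair_px minimum component size kept, in pixels
#'   (default 30).
#' @return A logical hair mask the size of the response map.
#' @export
hair_mask_from_response <- function(resp, dilation_radius_px = 1L,
                                    min_hair_px = 30L) {
  r <- if (is.list(resp)) resp$response else resp
  if (!is.matrix(r)) stop_derm("`resp` must be a matrix or the output of orientation_max_response()")
  rng <- range(r)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant response map: returning empty hair mask", call. = FALSE)
    return(matrix(FALSE, nrow(r), ncol(r)))
  }
  rn <- (r - rng[1]) / diff(rng)
  t <- otsu_threshold(rn)
  mask <- rn > t
  if (dilation_radius_px > 0 && any(mask))
    mask <- disk_rank_filter(mask * 1, as.integer(dilation_radius_px), 2L) > 0.5
  if (min_hair_px > 0 && any(mask)) {
    lab <- label_components8(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_hair_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Neighbourhood-based region filling (NBRF) inpainting
#'
#' Fills masked pixels radially inwards from the mask boundary: at each
#' iteration every masked pixel with at least one unmasked 8-neighbour
#' is assigned the per-channel mean of its unmasked 8-neighbours and
#' removed from the mask, until the mask is empty. Unmasked pixels are
#' returned unchanged.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param hair logical mask of pixels to fill (same H x W).
#' @return The inpainted image.
#' @export
nbrf_inpaint <- function(img, hair) {
  assert_image(img)
  assert_mask(hair, "hair")
  if (!identical(dim(hair), dim(img)[1:2]))
    stop_derm("mask dimensions differ from image")
  if (!any(hair)) return(img)
  if (all(hair)) stop_derm("mask covers the entire image; no background to estimate")
  out <- nbrf_fill(img, hair)
  array(clip01(out), dim = dim(img))
}

#' Detect and remove hairs from a dermoscopic image
#'
#' Full hair-removal stage: extract CIELAB luminance, compute the
#' orientation-maximum Gabor response on the inverted luminance,
#' binarize it into a hair mask, and inpaint the masked pixels with
#' [nbrf_inpaint()].
#'
#' @param img H x W x 3 sRGB array in \[0, 1\].
#' @param params a [gabor_params()] object.
#' @param dilation_radius_px,min_hair_px passed to
#'   [hair_mask_from_response()].
#' @return A list with `image` (inpainted), `hair_mask` (logical) and
#'   `response` (the orientation-maximum map).
#' @export
remove_hairs <- function(img, params = gabor_params(),
                         dilation_radius_px = 1L, min_hair_px = 30L) {
  assert_image(img)
  L <- extract_luminance(img)
  resp <- orientation_max_response(L, params)
  mask <- hair_mask_from_response(resp, dilation_radius_px, min_hair_px)
  inp <- if (any(mask)) nbrf_inpaint(img, mask) else img
  list(image = inp, hair_mask = mask, response = resp$response)
}
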