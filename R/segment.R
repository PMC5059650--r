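#' Morphological segmentation parameters
#'
#' Structuring-element radii and object-filter constants of the
#' segmentation stage. The method fixes the Otsu offset `kappa = 0.08`
#' and the object filter (area >= 20 px, solidity > 0.25); the disk
#' radii are implementation defaults calibrated on the synthetic
#' suite: median disk 5 px, opening disk 7 px (the reconstruction
#' marker), and a smaller 1 px disk for the final closing and erosion
#' (the grayscale erosion grows the dark lesion outward by its radius,
#' so the smallest disk minimizes boundary bias while still removing
#' fine noise).
#'
#' @param median_radius disk radius of the median filter (px).
#' @param open_radius disk radius of the grayscale opening that builds
#'   the reconstruction marker (px).
#' @param post_radius smaller disk radius of the final closing and
#'   erosion (px); must be below `open_radius`.
#' @param kappa offset subtracted from the Otsu threshold before
#'   binarization, in \[0, 0.5).
#' @param min_area_px minimum object area kept (px).
#' @param min_solidity minimum object solidity kept, in (0, 1].
#' @return An object of class `morpho_params`.
#' @export
morpho_params <- function(median_radius = 5L, open_radius = 7L,
                          post_radius = 1L, kappa = 0.08,
                          min_area_px = 20L, min_solidity = 0.25) {
  if (median_radius < 1L) stop_derm("`median_radius` must be >= 1")
  if (post_radius >= open_radius)
    stop_derm("`post_radius` must be smaller than `open_radius`")
  if (kappa < 0 || kappa >= 0.5) stop_derm("`kappa` must be in [0, 0.5)")
  if (min_solidity <= 0 || min_solidity > 1)
    stop_derm("`min_solidity` must be in (0, 1]")
  structure(list(median_radius = as.integer(median_radius),
                 open_radius = as.integer(open_radius),
                 post_radius = as.integer(post_radius), kappa = kappa,
                 min_area_px = as.integer(min_area_px),
                 min_solidity = min_solidity),
            class = "morpho_params")
}

#' @export
print.morpho_params <- function(x, ...) {
  cat("Morphology: median disk", x$median_radius, "px, opening disk",
      x$open_radius, "px, post disk", x$post_radius, "px\n",
      "kappa =", x$kappa, " min area =", x$min_area_px,
      "px  min solidity =", x$min_solidity, "\n")
  invisible(x)
}

#' Disk median filter
#'
#' Per-pixel median over a disk footprint of the given radius with
#' reflective borders; suppresses fine-level noise before the
#' morphological stage.
#'
#' @param L luminance matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return Filtered matrix.
#' @export
median_smooth <- function(L, radius = 5L) {
  if (radius < 1L) stop_derm("`radius` must be >= 1")
  if (!is.matrix(L)) stop_derm("`L` must be a matrix")
  disk_rank_filter(L, as.integer(radius), 0L)
}

## Grayscale opening/closing with a disk, via the Rcpp min/max filters
## (reflective borders throughout).
gray_open <- function(m, radius) {
  disk_rank_filter(disk_rank_filter(m, radius, 1L), radius, 2L)
}
gray_close <- function(m, radius) {
  disk_rank_filter(disk_rank_filter(m, radius, 2L), radius, 1L)
}

#' Opening-reconstruction smoothing
#'
#' Grayscale opening of the median-filtered luminance by
#' `disk(open_radius)` builds a marker; morphological
#' reconstruction-by-dilation (8-connectivity, iterated to its fixed
#' point) of that marker under the median-filtered image restores the
#' shapes of structures that survive the opening while removing small
#' bright peaks. A closing and an erosion by the smaller
#' `disk(post_radius)` then merge pixels at the lesion border and
#' remove residual fine noise.
#'
#' @param LM median-filtered luminance matrix.
#' @param params a [morpho_params()] object.
#' @return A list with `L_MC` (the final map), `L_O` (the marker) and
#'   `L_rec` (reconstruction before closing/erosion).
#' @export
reconstruct_open <- function(LM, params = morpho_params()) {
  if (!is.matrix(LM)) stop_derm("`LM` must be a matrix")
  LO <- gray_open(LM, params$open_radius)
  Lrec <- reconstruct_dilation(LO, LM)
  LMC <- disk_rank_filter(gray_close(Lrec, params$post_radius),
                          params$post_radius, 1L)
  list(L_MC = LMC, L_O = LO, L_rec = Lrec)
}

#' Offset Otsu binarization of the processed luminance
#'
#' Lesion pixels are dark after the sigmoid stretch, so the lesion
#' mask is `L_MC < t - kappa` with `t` the Otsu threshold of `L_MC`.
#' The offset `kappa` controls how boundary pixels in the smooth
#' lesion-skin transition are assigned.
#'
#' @param LMC processed luminance matrix.
#' @param kappa Otsu offset (default 0.08).
#' @return Logical lesion mask (before object filtering).
#' @export
binarize_lesion <- function(LMC, kappa = 0.08) {
  if (!is.matrix(LMC)) stop_derm("`LMC` must be a matrix")
  t <- suppressWarnings(otsu_threshold(LMC, range = range(c(0, 1, LMC))))
  if (is.na(t)) {
    warning("constant map: empty lesion mask", call. = FALSE)
    return(matrix(FALSE, nrow(LMC), ncol(LMC)))
  }
  LMC < t - kappa
}

## Solidity of one object: pixel area over the pixel area of its convex
## hull. The hull is taken over the four corners of every object pixel
## and rasterized by counting pixel centres inside or on the hull.
object_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(1)
  corners <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
                   c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  hull <- grDevices::chull(corners)
  hx <- corners[hull, 1]; hy <- corners[hull, 2]
  rr <- range(rows); cc <- range(cols)
  grid <- expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2])
  inside <- pracma::inpolygon(grid$r, grid$c, hx, hy, boundary = TRUE)
  hull_px <- sum(inside)
  if (hull_px < n) hull_px <- n     # rasterization guard
  n / hull_px
}

#' Filter connected components by area and solidity
#'
#' Labels the lesion mask with 8-connectivity and keeps objects with
#' area >= `min_area_px` *and* solidity > `min_solidity`; ragged,
#' speck-like noise fails one of the two. Interior holes of kept
#' objects are filled. Returns a `derm_segmentation` object.
#'
#' @param LB logical lesion mask from [binarize_lesion()].
#' @param params a [morpho_params()] object.
#' @param intermediates optional named list of per-stage maps to carry
#'   in the result.
#' @return An object of class `derm_segmentation`: `lesion_mask`
#'   (logical, holes filled), `objects` and `rejected` (data frames
#'   with label, area_px, solidity, bbox), `intermediates`.
#' @export
filter_objects <- function(LB, params = morpho_params(),
                           intermediates = list()) {
  assert_mask(LB, "LB")
  lab <- label_components8(LB)
  nobj <- max(lab)
  rows <- row(lab); cols <- col(lab)
  obj <- data.frame(label = integer(0), area_px = integer(0),
                    solidity = numeric(0), row0 = integer(0),
                    col0 = integer(0), row1 = integer(0), col1 = integer(0))
  kept <- obj; rejected <- obj
  keep_mask <- matrix(FALSE, nrow(LB), ncol(LB))
  if (nobj > 0) {
    for (k in seq_len(nobj)) {
      sel <- lab == k
      r <- rows[sel]; c <- cols[sel]
      area <- length(r)
      sol <- object_solidity(r, c)
      rec <- data.frame(label = k, area_px = area, solidity = sol,
                        row0 = min(r), col0 = min(c),
                        row1 = max(r) + 1L, col1 = max(c) + 1L)
      if (area >= params$min_area_px && sol > params$min_solidity) {
        kept <- rbind(kept, rec)
        keep_mask[sel] <- TRUE
      } else {
        rejected <- rbind(rejected, rec)
      }
    }
  }
  if (any(keep_mask)) {
    keep_mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(keep_mask * 1))) > 0.5
  } else {
    message("no lesion detected")
  }
  structure(list(lesion_mask = keep_mask, objects = kept,
                 rejected = rejected, intermediates = intermediates),
            class = "derm_segmentation")
}

#' Segment a lesion from an enhanced luminance map
#'
#' Composition of the segmentation stage: disk median filter,
#' opening-reconstruction smoothing, offset Otsu binarization, and
#' component filtering by area and solidity.
#'
#' @param L_enh enhanced (sigmoid-stretched) luminance matrix.
#' @param params a [morpho_params()] object.
#' @return A `derm_segmentation` object with intermediates `L_M`,
#'   `L_O`, `L_MC`, `L_B`.
#' @export
segment_lesion <- function(L_enh, params = morpho_params()) {
  if (!is.matrix(L_enh)) stop_derm("`L_enh` must be a matrix")
  LM <- median_smooth(L_enh, params$median_radius)
  rec <- reconstruct_open(LM, params)
  LB <- binarize_lesion(rec$L_MC, params$kappa)
  filter_objects(LB, params,
                 intermediates = list(L_M = LM, L_O = rec$L_O,
                                      L_MC = rec$L_MC, L_B = LB))
}

#' @export
print.derm_segmentation <- function(x, ...) {
  cat("Lesion segmentation:", sum(x$lesion_mask), "foreground px in",
      nrow(x$objects), "object(s);", nrow(x$rejected), "rejected\n")
  if (nrow(x$objects) > 0) {
    print(x$objects[, c("label", "area_px", "solidity")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.derm_segmentation <- function(x, ...) {
  graphics::image(t(x$lesion_mask[nrow(x$lesion_mask):1, ]),
                  col = c("grey20", "tomato"), axes = FALSE,
                  main = "lesion mask", ...)
  invisible(x)
}

#' Pixelwise segmentation metrics
#'
#' Confusion counts of a predicted lesion mask against ground truth
#' and the derived percentages: true detection rate
#' `TDR = 100 * TP / (TP + FN)`, false positive rate
#' `FPR = 100 * FP / (FP + TN)` and error rate
#' `ER = 100 * (FP + FN) / total`. A zero denominator yields 0 with a
#' warning.
#'
#' @param pred predicted logical mask.
#' @param truth ground-truth logical mask of the same size.
#' @return A list of class `derm_metrics`: `tp`, `tn`, `fp`, `fn`,
#'   `tdr_pct`, `fpr_pct`, `er_pct`.
#' @export
evaluate_mask <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop_derm("`pred` and `truth` dimensions differ")
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  rate <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, ": reporting 0", call. = FALSE)
      return(0)
    }
    100 * num / den
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 tdr_pct = rate(tp, tp + fn, "TDR"),
                 fpr_pct = rate(fp, fp + tn, "FPR"),
                 er_pct = rate(fp + fn, tp + tn + fp + fn, "ER")),
            class = "derm_metrics")
}

#' @export
print.derm_metrics <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\nTDR %.2f%%  FPR %.2f%%  ER %.2f%%\n",
              x$tp, x$tn, x$fp, x$fn, x$tdr_pct, x$fpr_pct, x$er_pct))
  invisible(x)
}
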