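#' Full pipeline configuration
#'
#' Aggregates every tunable of the three stages: the Gabor bank for
#' hair enhancement, the contrast/enhancement constants, the
#' morphological segmentation constants, and the Gaussian sigma of the
#' illumination model (`NULL` = `min(H, W) / 8` per image). The whole
#' object round-trips through a flat key-value text config
#' ([write_config()] / [read_config()]).
#'
#' @param gabor a [gabor_params()] object.
#' @param contrast a [contrast_params()] object.
#' @param morpho a [morpho_params()] object.
#' @param sigma_illum Gaussian sigma (px) for illumination estimation,
#'   or `NULL` for the per-image default.
#' @param hair_dilation_px,min_hair_px hair-mask post-processing, see
#'   [hair_mask_from_response()].
#' @param save_intermediates write per-stage maps next to the final
#'   mask in [run_pipeline()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gabor = gabor_params(),
                            contrast = contrast_params(),
                            morpho = morpho_params(),
                            sigma_illum = NULL,
                            hair_dilation_px = 1L, min_hair_px = 30L,
                            save_intermediates = FALSE) {
  stopifnot(inherits(gabor, "gabor_params"),
            inherits(contrast, "contrast_params"),
            inherits(morpho, "morpho_params"))
  structure(list(gabor = gabor, contrast = contrast, morpho = morpho,
                 sigma_illum = sigma_illum,
                 hair_dilation_px = as.integer(hair_dilation_px),
                 min_hair_px = as.integer(min_hair_px),
                 save_intermediates = isTRUE(save_intermediates)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Dermoscopy pipeline configuration\n")
  print(x$gabor); print(x$contrast); print(x$morpho)
  cat("sigma_illum:", if (is.null(x$sigma_illum)) "min(H, W) / 8"
      else x$sigma_illum, "\n")
  invisible(x)
}

config_flat <- function(cfg) {
  c(dilation_a = cfg$gabor$dilation_a,
    elongation_eps = cfg$gabor$elongation_eps,
    theta_step_deg = cfg$gabor$theta_step_deg,
    freq_r0_1 = cfg$gabor$freq_r0[1], freq_r0_2 = cfg$gabor$freq_r0[2],
    kernel_halfwidth = cfg$gabor$kernel_halfwidth,
    l_ref = cfg$contrast$l_ref, k_skin = cfg$contrast$k_skin,
    pct_lo = cfg$contrast$pct_lo, pct_hi = cfg$contrast$pct_hi,
    b_bits = cfg$contrast$b_bits, scale_p = cfg$contrast$scale_p,
    gain = cfg$contrast$gain,
    median_radius = cfg$morpho$median_radius,
    open_radius = cfg$morpho$open_radius,
    post_radius = cfg$morpho$post_radius, kappa = cfg$morpho$kappa,
    min_area_px = cfg$morpho$min_area_px,
    min_solidity = cfg$morpho$min_solidity,
    sigma_illum = if (is.null(cfg$sigma_illum)) NA_real_ else cfg$sigma_illum,
    hair_dilation_px = cfg$hair_dilation_px, min_hair_px = cfg$min_hair_px)
}

#' Write / read a pipeline configuration as flat text
#'
#' One `key = value` pair per line; `sigma_illum = NA` denotes the
#' per-image default.
#'
#' @param cfg a [pipeline_config()] object.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  v <- config_flat(cfg)
  writeLines(paste(names(v), "=", format(v, digits = 15, trim = TRUE)), path)
  invisible(NULL)
}

#' @rdname write_config
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  ln <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(ln, "\\s*=\\s*"))
  v <- stats::setNames(suppressWarnings(as.numeric(kv[, 2])), trimws(kv[, 1]))
  pipeline_config(
    gabor = gabor_params(v[["dilation_a"]], v[["elongation_eps"]],
                         v[["theta_step_deg"]],
                         c(v[["freq_r0_1"]], v[["freq_r0_2"]]),
                         v[["kernel_halfwidth"]]),
    contrast = contrast_params(v[["l_ref"]], v[["k_skin"]], v[["pct_lo"]],
                               v[["pct_hi"]], v[["b_bits"]], v[["scale_p"]],
                               v[["gain"]]),
    morpho = morpho_params(v[["median_radius"]], v[["open_radius"]],
                           v[["post_radius"]], v[["kappa"]],
                           v[["min_area_px"]], v[["min_solidity"]]),
    sigma_illum = if (is.na(v[["sigma_illum"]])) NULL else v[["sigma_illum"]],
    hair_dilation_px = v[["hair_dilation_px"]],
    min_hair_px = v[["min_hair_px"]])
}

#' Segment a dermoscopic image end to end
#'
#' Runs hair removal, luminance enhancement and lesion segmentation on
#' an in-memory image and returns the full `derm_segmentation` result
#' augmented with the hair mask and enhancement intermediates. The
#' pipeline is deterministic: identical input and configuration yield
#' identical output.
#'
#' @param img H x W x 3 sRGB array in \[0, 1\].
#' @param cfg a [pipeline_config()] object.
#' @return A `derm_segmentation` object; `$hair_mask`, `$inpainted`,
#'   `$enhanced` carry the earlier stages.
#' @examples
#' s <- generate_sample(synth_spec(height = 96, width = 96, seed = 7))
#' res <- segment_image(s$image)
#' print(res)
#' print(evaluate_mask(res$lesion_mask, s$lesion_truth))
#' @export
segment_image <- function(img, cfg = pipeline_config()) {
  assert_image(img)
  stopifnot(inherits(cfg, "pipeline_config"))
  hr <- remove_hairs(img, cfg$gabor, cfg$hair_dilation_px, cfg$min_hair_px)
  en <- enhance(hr$image, cfg$contrast, cfg$sigma_illum)
  res <- segment_lesion(en$L, cfg$morpho)
  res$hair_mask <- hr$hair_mask
  res$inpainted <- hr$image
  res$enhanced <- en
  res
}

#' Run the pipeline on an image file
#'
#' Loads `img_path`, runs [segment_image()], and writes the lesion
#' mask (`<stem>_mask.png`), the kept/rejected object table
#' (`<stem>_objects.csv`), and a run log with every effective
#' parameter; with `cfg$save_intermediates` also the hair mask,
#' inpainted image, equalized and stretched luminance maps. Errors are
#' reported with the failing stage name.
#'
#' @param img_path input image path (PNG/JPEG/TIFF).
#' @param cfg a [pipeline_config()] object.
#' @param out_dir output directory (created if missing).
#' @return The `derm_segmentation` result, invisibly.
#' @export
run_pipeline <- function(img_path, cfg = pipeline_config(), out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "load"
  res <- tryCatch({
    img <- load_image(img_path)
    stage <- "hair removal"
    hr <- remove_hairs(img, cfg$gabor, cfg$hair_dilation_px, cfg$min_hair_px)
    stage <- "enhancement"
    en <- enhance(hr$image, cfg$contrast, cfg$sigma_illum)
    stage <- "segmentation"
    r <- segment_lesion(en$L, cfg$morpho)
    r$hair_mask <- hr$hair_mask; r$inpainted <- hr$image; r$enhanced <- en
    r
  }, error = function(e) {
    stop_derm("pipeline failed at stage '", stage, "' for '", img_path,
              "': ", conditionMessage(e))
  })
  stem <- tools::file_path_sans_ext(basename(img_path))
  save_mask(res$lesion_mask, file.path(out_dir, paste0(stem, "_mask.png")))
  objs <- rbind(res$objects, res$rejected)
  objs$kept <- rep(c(TRUE, FALSE), c(nrow(res$objects), nrow(res$rejected)))
  utils::write.csv(objs, file.path(out_dir, paste0(stem, "_objects.csv")),
                   row.names = FALSE)
  if (cfg$save_intermediates) {
    save_mask(res$hair_mask, file.path(out_dir, paste0(stem, "_hairmask.png")))
    save_image(res$inpainted, file.path(out_dir, paste0(stem, "_inpainted.png")))
    save_image(res$enhanced$L_eq, file.path(out_dir, paste0(stem, "_leq.png")))
    save_image(res$enhanced$L, file.path(out_dir, paste0(stem, "_lstretch.png")))
  }
  v <- config_flat(cfg)
  writeLines(c(paste0("input: ", img_path),
               paste0("delta: ", format(res$enhanced$delta, digits = 15)),
               paste(names(v), "=", format(v, digits = 15, trim = TRUE))),
             file.path(out_dir, paste0(stem, "_run.log")))
  invisible(res)
}

#' Evaluate predicted masks against ground truth
#'
#' Pairs mask files by filename across two directories, computes
#' pixelwise metrics per image and their means. Unmatched filenames
#' are skipped with a warning.
#'
#' @param pred_dir directory of predicted mask PNGs.
#' @param truth_dir directory of ground-truth mask PNGs with matching
#'   filenames.
#' @param out_prefix optional path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json` when given.
#' @return A data frame of per-image metrics with a `mean` attribute
#'   (named vector of mean tdr/fpr/er).
#' @export
run_eval <- function(pred_dir, truth_dir, out_prefix = NULL) {
  pf <- list.files(pred_dir, pattern = "\\.png$", ignore.case = TRUE)
  tf <- list.files(truth_dir, pattern = "\\.png$", ignore.case = TRUE)
  common <- intersect(pf, tf)
  missing <- union(setdiff(pf, tf), setdiff(tf, pf))
  if (length(missing))
    warning("skipping unmatched filename(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  if (!length(common)) stop_derm("no matching mask filenames across directories")
  rows <- lapply(common, function(f) {
    m <- evaluate_mask(load_mask(file.path(pred_dir, f)),
                       load_mask(file.path(truth_dir, f)))
    data.frame(file = f, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               tdr_pct = m$tdr_pct, fpr_pct = m$fpr_pct, er_pct = m$er_pct)
  })
  tab <- do.call(rbind, rows)
  mn <- c(tdr_pct = mean(tab$tdr_pct), fpr_pct = mean(tab$fpr_pct),
          er_pct = mean(tab$er_pct))
  attr(tab, "mean") <- mn
  if (!is.null(out_prefix)) {
    utils::write.csv(tab, paste0(out_prefix, ".csv"), row.names = FALSE)
    jsonlite::write_json(list(per_image = tab, mean = as.list(mn)),
                         paste0(out_prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  tab
}
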