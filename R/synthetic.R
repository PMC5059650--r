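#' Specification of a synthetic dermoscopy sample
#'
#' Describes one rendered sample: tan skin base with spatially
#' correlated noise, an optional radially perturbed elliptical lesion
#' with a soft edge and lowered tone, dark curved hairs, bright gel
#' bubbles, saturated specular spots and a multiplicative illumination
#' gradient. Every random choice is driven by `seed`.
#'
#' @param height,width image size in pixels (default 256 x 256).
#' @param seed integer RNG seed.
#' @param skin_rgb_mean mean sRGB skin tone (default a light tan whose
#'   CIELAB L* is about 0.75 on the unit scale).
#' @param skin_noise_sd standard deviation of the correlated skin
#'   texture noise (default 0.02).
#' @param illum_gradient_strength multiplicative illumination falloff
#'   amplitude in \[0, 0.5\] (default 0).
#' @param lesion list: `present`, `center` (row, col; NULL = jittered
#'   centre), `radii` (px; NULL = drawn in 35-55), `boundary_irregularity`
#'   (default 0.15), `tone_drop` in \[0.1, 0.6\] (default 0.45),
#'   `edge_softness_px` (default 2.5).
#' @param hairs list: `count` (default 0), `width_px` (1-4, default 2),
#'   `darkness` (default 0.65), `curvature` (default 0.35).
#' @param bubbles list: `count` (default 0), `radius_range` (default
#'   c(4, 10)).
#' @param specular list: `count` (default 0), `intensity` (default 0.5).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(height = 256L, width = 256L, seed = 1L,
                       skin_rgb_mean = c(0.87, 0.64, 0.55),
                       skin_noise_sd = 0.02,
                       illum_gradient_strength = 0,
                       lesion = list(), hairs = list(), bubbles = list(),
                       specular = list()) {
  if (height < 32L || width < 32L)
    stop_derm("synthetic images must be at least 32 x 32")
  if (illum_gradient_strength < 0 || illum_gradient_strength > 0.5)
    stop_derm("`illum_gradient_strength` must be in [0, 0.5]")
  les <- utils::modifyList(list(present = TRUE, center = NULL, radii = NULL,
                                boundary_irregularity = 0.15,
                                tone_drop = 0.45, edge_softness_px = 2.5),
                           lesion)
  if (les$tone_drop < 0.1 || les$tone_drop > 0.6)
    stop_derm("`lesion$tone_drop` must be in [0.1, 0.6]")
  hr <- utils::modifyList(list(count = 0L, width_px = 2L, darkness = 0.65,
                               curvature = 0.35), hairs)
  if (hr$width_px < 1L || hr$width_px > 4L)
    stop_derm("`hairs$width_px` must be in 1..4")
  bb <- utils::modifyList(list(count = 0L, radius_range = c(4, 10)), bubbles)
  sp <- utils::modifyList(list(count = 0L, intensity = 0.5), specular)
  structure(list(height = as.integer(height), width = as.integer(width),
                 seed = as.integer(seed), skin_rgb_mean = skin_rgb_mean,
                 skin_noise_sd = skin_noise_sd,
                 illum_gradient_strength = illum_gradient_strength,
                 lesion = les, hairs = hr, bubbles = bb, specular = sp),
            class = "synth_spec")
}

## Smooth low-frequency noise field: white noise blurred by a Gaussian,
## rescaled to the requested sd.
correlated_noise <- function(H, W, sd, sigma = 3) {
  n <- matrix(stats::rnorm(H * W), H, W)
  s <- conv2_reflect(n, gaussian_kernel(sigma))
  if (stats::sd(s) > 0) s <- s / stats::sd(s)
  s * sd
}

## Radially perturbed ellipse: soft alpha in [0,1] and hard truth mask.
render_lesion <- function(H, W, les) {
  ctr <- les$center
  if (is.null(ctr)) ctr <- c(H / 2 + stats::runif(1, -0.06, 0.06) * H,
                             W / 2 + stats::runif(1, -0.06, 0.06) * W)
  radii <- les$radii
  if (is.null(radii)) radii <- sort(stats::runif(2, 0.14, 0.21)) * min(H, W)
  if (2 * max(radii) >= min(H, W))
    stop_derm("lesion larger than the frame")
  rot <- stats::runif(1, 0, pi)
  nharm <- 4L
  amp <- stats::runif(nharm, 0, les$boundary_irregularity) / seq_len(nharm)
  ph <- stats::runif(nharm, 0, 2 * pi)
  rr <- matrix(seq_len(H), H, W) - ctr[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  x <- cos(rot) * cc + sin(rot) * rr
  y <- -sin(rot) * cc + cos(rot) * rr
  phi <- atan2(y / radii[1], x / radii[2])
  pert <- 1
  for (k in seq_len(nharm))
    pert <- pert + amp[k] * sin((k + 1) * phi + ph[k])
  ## signed "radial" distance: > 0 outside the perturbed boundary
  rho <- sqrt((x / radii[2])^2 + (y / radii[1])^2)
  d <- (rho - pert) * mean(radii)          # approx distance in px
  alpha <- stats::pnorm(-d / max(les$edge_softness_px, 1e-6))
  list(alpha = alpha, truth = d < 0, center = ctr, radii = radii,
       rot = rot, amp = amp, ph = ph)
}

## Quadratic Bezier hair strokes stamped as disks; returns logical mask.
render_hairs <- function(H, W, hr) {
  mask <- matrix(FALSE, H, W)
  if (hr$count < 1L) return(mask)
  hrad <- hr$width_px / 2
  rad <- ceiling(hrad) + 1L
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  edge_point <- function() {
    side <- sample.int(4L, 1L)
    switch(side,
           c(1, stats::runif(1, 1, W)),
           c(H, stats::runif(1, 1, W)),
           c(stats::runif(1, 1, H), 1),
           c(stats::runif(1, 1, H), W))
  }
  for (i in seq_len(hr$count)) {
    p0 <- edge_point(); p2 <- edge_point()
    mid <- (p0 + p2) / 2
    perp <- c(-(p2 - p0)[2], (p2 - p0)[1])
    nr <- sqrt(sum(perp^2)); if (nr < 1) next
    p1 <- mid + perp / nr * stats::runif(1, -1, 1) * hr$curvature *
      sqrt(sum((p2 - p0)^2))
    tt <- seq(0, 1, length.out = 4L * ceiling(sqrt(sum((p2 - p0)^2))) + 8L)
    br <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
    bc <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
    rb <- round(br); cb <- round(bc)
    for (k in seq_len(nrow(offs))) {
      ri <- rb + offs$dr[k]; ci <- cb + offs$dc[k]
      ## pixel centre within hrad of the (fractional) centreline point
      hit <- (ri - br)^2 + (ci - bc)^2 <= hrad^2
      ok <- hit & ri >= 1 & ri <= H & ci >= 1 & ci <= W
      mask[cbind(ri[ok], ci[ok])] <- TRUE
    }
  }
  mask
}

#' Render a synthetic dermoscopy sample
#'
#' Deterministically renders a sample from its specification. The
#' render order is: skin base with correlated noise, lesion composite,
#' bubbles and specular spots, multiplicative illumination gradient,
#' then hairs last, so that `hairfree_image` differs from `image`
#' exactly on the hair pixels.
#'
#' @param spec a [synth_spec()] object.
#' @return A list of class `synth_sample`: `image`, `hairfree_image`
#'   (H x W x 3 arrays), `lesion_truth`, `hair_truth` (logical
#'   matrices), `lesion_geom` (boundary-curve parameters: centre,
#'   radii, rotation, harmonic amplitudes/phases) and `spec`.
#' @export
generate_sample <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  H <- spec$height; W <- spec$width
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)

  base <- array(rep(spec$skin_rgb_mean, each = H * W), dim = c(H, W, 3))
  tex <- correlated_noise(H, W, spec$skin_noise_sd)
  for (c in 1:3) base[, , c] <- base[, , c] + tex

  lesion_truth <- matrix(FALSE, H, W)
  lesion_geom <- NULL
  if (isTRUE(spec$lesion$present)) {
    les <- render_lesion(H, W, spec$lesion)
    lesion_truth <- les$truth
    lesion_geom <- les[c("center", "radii", "rot", "amp", "ph")]
    ## darker, browner interior: multiplicative tone drop, strongest in red
    drop <- spec$lesion$tone_drop
    fac <- c(1, 1.15, 1.25)
    for (c in 1:3)
      base[, , c] <- base[, , c] * (1 - pmin(drop * fac[c], 0.9) * les$alpha)
  }
  if (spec$bubbles$count > 0) {
    for (i in seq_len(spec$bubbles$count)) {
      ctr <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      rad <- stats::runif(1, spec$bubbles$radius_range[1],
                          spec$bubbles$radius_range[2])
      rr <- matrix(seq_len(H), H, W) - ctr[1]
      cc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
      ring <- exp(-((sqrt(rr^2 + cc^2) - rad)^2) / (2 * 1.2^2)) * 0.15
      for (c in 1:3) base[, , c] <- base[, , c] + ring
    }
  }
  if (spec$specular$count > 0) {
    for (i in seq_len(spec$specular$count)) {
      ctr <- c(stats::runif(1, H * 0.1, H * 0.9),
               stats::runif(1, W * 0.1, W * 0.9))
      rad <- stats::runif(2, 2, 5)
      rr <- (matrix(seq_len(H), H, W) - ctr[1]) / rad[1]
      cc <- (matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]) / rad[2]
      blob <- exp(-(rr^2 + cc^2) / 2) * spec$specular$intensity
      for (c in 1:3) base[, , c] <- base[, , c] + blob
    }
  }
  if (spec$illum_gradient_strength > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    rr <- (matrix(seq_len(H), H, W) - 1) / (H - 1) - 0.5
    cc <- (matrix(seq_len(W), H, W, byrow = TRUE) - 1) / (W - 1) - 0.5
    ramp <- cos(ang) * rr + sin(ang) * cc           # in [-0.71, 0.71]
    vign <- rr^2 + cc^2                             # centre vignette
    g <- 1 - spec$illum_gradient_strength * (0.5 + 0.7 * ramp + 0.6 * vign)
    for (c in 1:3) base[, , c] <- base[, , c] * g
  }
  hairfree <- clip01(base)

  hair_truth <- render_hairs(H, W, spec$hairs)
  img <- hairfree
  if (any(hair_truth)) {
    hair_rgb <- c(0.10, 0.08, 0.07)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[hair_truth] <- (1 - spec$hairs$darkness) * ch[hair_truth] +
        spec$hairs$darkness * hair_rgb[c]
      img[, , c] <- ch
    }
  }
  structure(list(image = clip01(img), hairfree_image = hairfree,
                 lesion_truth = lesion_truth, hair_truth = hair_truth,
                 lesion_geom = lesion_geom, spec = spec),
            class = "synth_sample")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.synth_sample <- function(x, ...) {
  cat("Synthetic dermoscopy sample", x$spec$height, "x", x$spec$width,
      "(seed", paste0(x$spec$seed, ")"), "\n  lesion px:",
      sum(x$lesion_truth), " hair px:", sum(x$hair_truth), "\n")
  invisible(x)
}

#' Generate a reproducible suite of synthetic samples
#'
#' Derives one seed per sample from the suite seed by a fixed affine
#' counter scheme (`(seed * 10007 + 97 * i) mod (2^31 - 1)`), so any
#' sample can be re-rendered in isolation. The difficulty toggles the
#' artifact classes:
#' \describe{
#'   \item{clean}{lesion only}
#'   \item{hairy}{lesion + 12 hairs}
#'   \item{gradient}{lesion + illumination gradient 0.25}
#'   \item{full}{lesion + hairs + gradient + 3 bubbles + 2 specular
#'     spots}
#' }
#'
#' @param n number of samples (>= 1).
#' @param seed suite seed.
#' @param difficulty one of "clean", "hairy", "gradient", "full".
#' @param height,width sample size (default 256).
#' @return A list of `synth_sample` objects.
#' @export
generate_suite <- function(n, seed = 1L,
                           difficulty = c("clean", "hairy", "gradient", "full"),
                           height = 256L, width = 256L) {
  if (n < 1L) stop_derm("`n` must be >= 1")
  difficulty <- match.arg(difficulty)
  hairs <- if (difficulty %in% c("hairy", "full")) list(count = 12L) else list()
  grad <- if (difficulty %in% c("gradient", "full")) 0.25 else 0
  bub <- if (difficulty == "full") list(count = 3L) else list()
  spc <- if (difficulty == "full") list(count = 2L) else list()
  lapply(seq_len(n), function(i) {
    si <- (as.numeric(seed) * 10007 + 97 * i) %% (2^31 - 1)
    generate_sample(synth_spec(height = height, width = width,
                               seed = as.integer(si),
                               illum_gradient_strength = grad,
                               hairs = hairs, bubbles = bub,
                               specular = spc))
  })
}
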