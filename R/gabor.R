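#' Gabor wavelet bank parameters
#'
#' Parameters of the oriented 2-D Gabor wavelet bank used to enhance
#' hair structures: a complex exponential of frequency vector `freq_r0`
#' modulated by an anisotropic Gaussian envelope elongated by
#' `elongation_eps` along the filter axis, evaluated at a single
#' dilation `dilation_a` over orientations `0, theta_step_deg, ...,
#' 180 - theta_step_deg` degrees.
#'
#' @param dilation_a wavelet dilation (scale) in pixels; default 2.5.
#' @param elongation_eps envelope elongation, >= 1; default 3.
#' @param theta_step_deg orientation step in degrees; must divide 180
#'   evenly; default 15.
#' @param freq_r0 length-2 frequency vector of the complex exponential
#'   (radians per pixel at unit scale); default `c(0, 3)`.
#' @param kernel_halfwidth half-width of the sampled kernel in pixels;
#'   default `ceiling(3 * dilation_a * max(sqrt(elongation_eps), 1))`
#'   so at least 3 envelope standard deviations are covered.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(dilation_a = 2.5, elongation_eps = 3,
                         theta_step_deg = 15, freq_r0 = c(0, 3),
                         kernel_halfwidth = NULL) {
  if (dilation_a <= 0) stop_derm("`dilation_a` must be positive")
  if (elongation_eps < 1) stop_derm("`elongation_eps` must be >= 1")
  if (theta_step_deg <= 0 || abs(180 / theta_step_deg -
                                 round(180 / theta_step_deg)) > 1e-9)
    stop_derm("`theta_step_deg` must divide 180 evenly")
  if (length(freq_r0) != 2L || !all(is.finite(freq_r0)))
    stop_derm("`freq_r0` must be a finite 2-vector")
  if (is.null(kernel_halfwidth))
    kernel_halfwidth <- ceiling(3 * dilation_a * max(sqrt(elongation_eps), 1))
  kernel_halfwidth <- as.integer(kernel_halfwidth)
  if (kernel_halfwidth < ceiling(3 * dilation_a))
    stop_derm("`kernel_halfwidth` must be at least 3 * dilation_a")
  structure(list(dilation_a = dilation_a, elongation_eps = elongation_eps,
                 theta_step_deg = theta_step_deg, freq_r0 = freq_r0,
                 kernel_halfwidth = kernel_halfwidth),
            class = "gabor_params")
}

#' @export
print.gabor_params <- function(x, ...) {
  cat("Gabor bank: a =", x$dilation_a, " eps =", x$elongation_eps,
      " theta step =", x$theta_step_deg, "deg  R0 = [",
      paste(x$freq_r0, collapse = ", "), "]  halfwidth =",
      x$kernel_halfwidth, "px\n")
  invisible(x)
}

bank_thetas <- function(params) seq(0, 180 - params$theta_step_deg,
                                    by = params$theta_step_deg)

#' Build one oriented Gabor kernel
#'
#' Samples the complex Gabor wavelet
#' \deqn{\Phi(u) = \exp(i R_0 \cdot u)\,\exp(-\tfrac12 |A u|^2),\quad
#'       A = \mathrm{diag}(\epsilon^{-1/2}, 1),}
#' at \eqn{u = r_{-\theta} x / a} on an integer grid of half-width
#' `kernel_halfwidth` (x = (column, row) offsets from the centre). The
#' complex mean is subtracted so the DC response is exactly zero, and
#' the kernel is scaled to unit L2 norm (within one image only relative
#' responses matter, so any fixed positive normalization is
#' equivalent).
#'
#' @param params a [gabor_params()] object.
#' @param theta_deg orientation in degrees, in \[0, 180).
#' @return A complex matrix of size `(2 * halfwidth + 1)^2`.
#' @export
build_gabor_kernel <- function(params, theta_deg) {
  stopifnot(inherits(params, "gabor_params"))
  if (theta_deg < 0 || theta_deg >= 180)
    stop_derm("`theta_deg` must be in [0, 180)")
  hw <- params$kernel_halfwidth
  a <- params$dilation_a
  eps <- params$elongation_eps
  th <- theta_deg * pi / 180
  off <- -hw:hw
  cc <- matrix(off, 2 * hw + 1, 2 * hw + 1, byrow = TRUE)   # column offset
  rr <- matrix(off, 2 * hw + 1, 2 * hw + 1)                 # row offset
  u1 <- (cos(th) * cc + sin(th) * rr) / a
  u2 <- (-sin(th) * cc + cos(th) * rr) / a
  env <- exp(-0.5 * (u1^2 / eps + u2^2))
  k <- exp(1i * (params$freq_r0[1] * u1 + params$freq_r0[2] * u2)) * env
  k <- k - mean(k)                       # DC-free
  k / sqrt(sum(Mod(k)^2))                # unit L2 norm
}

#' Maximum oriented Gabor response
#'
#' Convolves the *inverted* luminance map `1 - L` (hairs are dark on
#' bright skin, so inversion makes them positive-going) with every
#' orientation of the Gabor bank, takes the complex modulus, and
#' returns the per-pixel maximum over orientations together with the
#' attaining orientation. Borders are handled by reflection.
#'
#' @param L luminance matrix in \[0, 1\].
#' @param params a [gabor_params()] object.
#' @return A list with `response` (H x W, >= 0) and `argmax_theta`
#'   (H x W, degrees in \[0, 180)).
#' @export
orientation_max_response <- function(L, params = gabor_params()) {
  assert_lum(L)
  stopifnot(inherits(params, "gabor_params"))
  inv <- 1 - L
  thetas <- bank_thetas(params)
  best <- matrix(-Inf, nrow(L), ncol(L))
  arg <- matrix(0, nrow(L), ncol(L))
  for (th in thetas) {
    k <- build_gabor_kernel(params, th)
    re <- conv2_reflect(inv, Re(k))
    im <- conv2_reflect(inv, Im(k))
    m <- sqrt(re^2 + im^2)
    sel <- m > best
    best[sel] <- m[sel]
    arg[sel] <- th
  }
  list(response = best, argmax_theta = arg)
}
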