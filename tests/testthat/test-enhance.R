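test_that("background mask implements the inflated-Otsu rule", {
  L <- bimodal_map(32, 32, lo = 0.3, hi = 0.9, frac_hi = 0.6, seed = 41)
  t <- otsu_threshold(L)
  expect_gt(t, 0.3); expect_lt(t, 0.9)
  bg <- background_mask(L)
  expect_identical(bg, L > 1.2 * t)
  ## the dark mode is excluded whenever 1.2 t exceeds it
  expect_false(any(bg[L == 0.3]))

  expect_error(suppressWarnings(background_mask(matrix(0.6, 16, 16))),
               "background")
})

test_that("normalized convolution reproduces constants on any support", {
  ## full support, constant field
  L <- matrix(0.37, 24, 24)
  bg <- matrix(TRUE, 24, 24)
  expect_lt(max(abs(smoothed_background(L, bg, 3) - 0.37)), 1e-10)
  ## checkerboard support, constant field
  cb <- (row(L) + col(L)) %% 2 == 0
  expect_lt(max(abs(smoothed_background(L, cb, 3) - 0.37)), 1e-10)
  ## random support vs directly computed two-convolution quotient
  set.seed(42)
  L2 <- matrix(runif(24 * 24), 24, 24)
  sup <- matrix(runif(24 * 24) > 0.4, 24, 24)
  got <- smoothed_background(L2, sup, 2)
  k <- dermseg:::gaussian_kernel(2)
  num <- Re(oracle_conv2(L2 * sup, k))
  den <- Re(oracle_conv2(sup * 1, k))
  expect_lt(max(abs(got[den >= 1e-8] - (num / den)[den >= 1e-8])), 1e-8)
})

test_that("full-support smoothing equals plain Gaussian smoothing", {
  set.seed(43)
  L <- matrix(runif(32 * 32), 32, 32)
  bg <- matrix(TRUE, 32, 32)
  plain <- dermseg:::conv2_reflect(L, dermseg:::gaussian_kernel(4))
  expect_lt(max(abs(smoothed_background(L, bg, 4) - plain)), 1e-10)
})

test_that("illumination estimation honours the good-fit tolerance", {
  L <- matrix(0.55, 32, 32)
  bg <- matrix(TRUE, 32, 32)
  uL <- smoothed_background(L, bg, 4)
  im <- illumination_estimate(L, uL, bg, 4)
  expect_true(all(im$Gfm))
  expect_lt(max(abs(im$EL - 0.55)), 1e-10)

  ## |uL - L| just over 0.05 everywhere -> fallback to global mean
  uL2 <- L + 0.06
  expect_warning(im2 <- illumination_estimate(L, uL2, bg, 4), "good-fit")
  expect_false(any(im2$Gfm))
  expect_equal(max(im2$EL), min(im2$EL))
})

test_that("a smooth multiplicative gradient is recovered", {
  H <- 128
  g <- outer(seq(0.8, 1.1, length.out = H), seq(0.9, 1.05, length.out = H))
  Lg <- 0.6 * g / max(g)
  bg <- matrix(TRUE, H, H)
  uL <- smoothed_background(Lg, bg, H / 8)
  im <- illumination_estimate(Lg, uL, bg, H / 8)
  expect_lt(mean(abs(im$EL - Lg) / Lg), 0.05)
})

test_that("equalization identities hold", {
  set.seed(44)
  L <- matrix(runif(16 * 16, 0.1, 0.9), 16, 16)
  ## E_L == L -> everything lands on l_ref
  expect_lt(max(abs(equalize(L, L) - 0.59)), 1e-12)
  ## L = 0 stays 0; ratio 2 clips at 1
  expect_identical(equalize(matrix(0, 8, 8), matrix(0.5, 8, 8)), matrix(0, 8, 8))
  expect_identical(equalize(matrix(1, 8, 8), matrix(0.5, 8, 8)), matrix(1, 8, 8))
  ## E_L == l_ref leaves L unchanged (up to clipping)
  expect_lt(max(abs(equalize(L, matrix(0.59, 16, 16)) - L)), 1e-12)
})

test_that("percentile normalization maps the window onto [0, k]", {
  L <- matrix(seq(0, 1, length.out = 10000), 100, 100)
  out <- percentile_normalize(L)
  expect_gte(min(out), 0)
  expect_equal(max(out), 0.75, tolerance = 1e-12)
  expect_true(all(diff(out[order(L)]) >= 0))
  p <- stats::quantile(L, c(0.01, 0.99), names = FALSE)
  i1 <- which.min(abs(L - p[1])); i99 <- which.min(abs(L - p[2]))
  expect_equal(out[i1], 0, tolerance = 1e-3)
  expect_equal(out[i99], 0.75, tolerance = 1e-3)

  expect_error(percentile_normalize(matrix(0.5, 16, 16)), "degenerate")
})

test_that("the adaptive cut-off picks the scaled modal-bin centre", {
  set.seed(45)
  x <- matrix(0.75, 50, 40)
  x[1:5, ] <- runif(200, 0, 0.5)           # 10% elsewhere
  expect_equal(adaptive_cutoff(x), 0.88 * 12.5 / 16, tolerance = 1e-12)
  expect_equal(adaptive_cutoff(x), 0.6875)

  hi <- matrix(runif(400, 0.94, 1), 20, 20)
  expect_equal(adaptive_cutoff(hi), 0.88 * 15.5 / 16, tolerance = 1e-12)
  expect_equal(adaptive_cutoff(hi), 0.8525)

  ## two equal modes -> brighter bin wins
  tie <- matrix(c(rep(0.53, 200), rep(0.78, 200)), 20, 20)
  expect_equal(adaptive_cutoff(tie), 0.88 * 12.5 / 16, tolerance = 1e-12)
})

test_that("the adaptive cut-off agrees with a brute-force histogram", {
  set.seed(46)
  for (i in 1:200) {
    x <- matrix(runif(64, 0, 1)^runif(1, 0.3, 3), 8, 8)
    expect_identical(adaptive_cutoff(x), oracle_cutoff(x))
  }
})

test_that("sigmoid stretch has the documented fixed points and monotonicity", {
  d <- 0.55
  expect_equal(sigmoid_stretch(matrix(d, 8, 8), d)[1, 1], 0.5,
               tolerance = 1e-12)
  expect_equal(sigmoid_stretch(matrix(d + 0.23, 8, 8), d)[1, 1],
               1 / (1 + exp(-2.3)), tolerance = 1e-12)
  ## large gain drives sub-cut-off values to 0
  expect_lt(sigmoid_stretch(matrix(d - 0.1, 8, 8), d, gain = 500)[1, 1], 1e-12)
  ## order preserving
  set.seed(47)
  x <- matrix(runif(256), 16, 16)
  y <- sigmoid_stretch(x, d)
  expect_true(all(diff(y[order(x)]) >= 0))
  expect_true(all(y > 0 & y < 1))
})

test_that("enhancement reduces skin luminance variation and keeps contrast", {
  s <- generate_sample(synth_spec(seed = 48, illum_gradient_strength = 0.3))
  en <- enhance(s$image)
  skin <- !s$lesion_truth
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(en$L_eq[skin]), cv(en$L_raw[skin]))
  gap_before <- stats::median(en$L_norm[skin]) -
    stats::median(en$L_norm[s$lesion_truth])
  gap_after <- stats::median(en$L[skin]) -
    stats::median(en$L[s$lesion_truth])
  expect_gte(gap_after, gap_before)
  expect_identical(dim(en$L), dim(s$lesion_truth))
  expect_true(all(en$L > 0 & en$L < 1))
})
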