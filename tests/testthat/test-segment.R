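test_that("disk median filtering matches a per-pixel sort oracle", {
  expect_identical(median_smooth(matrix(0.3, 12, 12), 3L),
                   matrix(0.3, 12, 12))
  ## a single outlier in a constant field is rejected
  m <- matrix(0.2, 16, 16); m[8, 8] <- 1
  expect_identical(median_smooth(m, 2L), matrix(0.2, 16, 16))

  set.seed(51)
  r <- matrix(runif(16 * 16), 16, 16)
  for (rad in c(2L, 3L))
    expect_equal(median_smooth(r, rad), oracle_median_disk(r, rad),
                 tolerance = 1e-14)
})

test_that("reconstruction equals the fixed point of geodesic dilation", {
  set.seed(52)
  for (i in 1:4) {
    mask <- matrix(runif(32 * 32), 32, 32)
    marker <- mask * matrix(runif(32 * 32), 32, 32)
    got <- dermseg:::reconstruct_dilation(marker, mask)
    expect_identical(got, oracle_reconstruct(marker, mask))
    expect_true(all(got <= mask))
    expect_true(all(got >= marker))
  }
  expect_error(dermseg:::reconstruct_dilation(matrix(1, 4, 4),
                                              matrix(0, 4, 4)), "<= mask")
})

test_that("opening-reconstruction keeps large domes and levels small ones", {
  flat <- matrix(0.2, 32, 32)
  expect_lt(max(abs(reconstruct_open(flat)$L_MC - 0.2)), 1e-12)

  ## flat-topped dome: plateau at 0.8 with linear flanks
  dome <- function(r0, flank = 8) {
    m <- matrix(0.2, 64, 64)
    d <- sqrt((row(m) - 32)^2 + (col(m) - 32)^2)
    m + 0.6 * pmax(pmin((r0 - d) / flank, 1), 0)
  }
  p <- morpho_params()
  small <- reconstruct_open(dome(4), p)       # extent < opening disk
  expect_lt(max(small$L_rec) - 0.2, 1e-6)
  big <- reconstruct_open(dome(28), p)        # plateau radius 20 >> disk 7
  expect_equal(max(big$L_rec), 0.8, tolerance = 1e-6)
  ## reconstruction never exceeds its mask
  expect_true(all(big$L_rec <= dome(28) + 1e-12))
})

test_that("binarization uses the offset Otsu rule on the dark side", {
  L <- bimodal_map(32, 32, lo = 0.2, hi = 0.9, frac_hi = 0.75, seed = 53)
  t <- otsu_threshold(L)
  expect_true(t - 0.08 > 0.2)               # dark mode below the cut
  mask <- binarize_lesion(L)
  expect_identical(mask, L < t - 0.08)
  expect_identical(mask, L == 0.2)

  ## uniformly bright input -> empty mask
  expect_false(any(binarize_lesion(matrix(c(0.8, 0.9), 16, 16))))
  expect_warning(binarize_lesion(matrix(0.5, 16, 16)), "constant")
})

test_that("object filtering enforces area and solidity rules", {
  p <- morpho_params()
  ## 10-px object alone: rejected on area
  m <- matrix(FALSE, 32, 32); m[5, 5:14] <- TRUE
  r1 <- suppressMessages(filter_objects(m, p))
  expect_false(any(r1$lesion_mask))
  expect_identical(nrow(r1$rejected), 1L)

  ## filled 20 x 20 square: kept, solidity exactly 1
  sq <- matrix(FALSE, 40, 40); sq[10:29, 10:29] <- TRUE
  r2 <- filter_objects(sq, p)
  expect_identical(r2$lesion_mask, sq)
  expect_identical(r2$objects$solidity, 1)
  expect_identical(r2$objects$area_px, 400L)

  ## plus-sign pentomino: solidity 5/9, area 5 -> rejected
  pl <- matrix(FALSE, 16, 16)
  pl[8, 7:9] <- TRUE; pl[7:9, 8] <- TRUE
  r3 <- suppressMessages(filter_objects(pl, p))
  expect_equal(r3$rejected$solidity, 5 / 9, tolerance = 1e-12)
  expect_identical(nrow(r3$objects), 0L)
  expect_equal(r3$rejected$solidity, oracle_solidity(pl), tolerance = 1e-12)

  ## holes of kept objects are filled; kept and rejected are disjoint
  ring <- matrix(FALSE, 40, 40); ring[10:29, 10:29] <- TRUE
  ring[15:24, 15:24] <- FALSE
  r4 <- filter_objects(ring, p)
  expect_true(all(r4$lesion_mask[15:24, 15:24]))
  expect_identical(intersect(r4$objects$label, r4$rejected$label), integer(0))
})

test_that("segmentation finds the drawn lesion and nothing else", {
  s <- generate_sample(synth_spec(seed = 54))
  en <- enhance(s$image)
  res <- segment_lesion(en$L)
  expect_identical(nrow(res$objects), 1L)
  truth_c <- colMeans(which(s$lesion_truth, arr.ind = TRUE))
  got_c <- colMeans(which(res$lesion_mask, arr.ind = TRUE))
  expect_lt(sqrt(sum((truth_c - got_c)^2)), 5)

  ## no lesion drawn -> "no lesion detected"
  s0 <- generate_sample(synth_spec(seed = 55,
                                   lesion = list(present = FALSE),
                                   skin_noise_sd = 0.01))
  L0 <- extract_luminance(s0$image)
  expect_message(r0 <- segment_lesion(L0), "no lesion")
  expect_false(any(r0$lesion_mask))

  ## determinism
  res2 <- segment_lesion(en$L)
  expect_identical(res$lesion_mask, res2$lesion_mask)
})

test_that("evaluation metrics implement the stated formulas", {
  t <- matrix(FALSE, 25, 40); t[5:14, 5:14] <- TRUE
  m <- evaluate_mask(t, t)
  expect_identical(c(m$tdr_pct, m$fpr_pct, m$er_pct), c(100, 0, 0))

  ## constructed confusion: TP 90, FN 10, FP 5, TN 895
  truth <- matrix(FALSE, 25, 40); truth[1:4, 1:25] <- TRUE  # 100 px
  pred <- truth; pred[4, 16:25] <- FALSE                    # 10 FN
  pred[20, 1:5] <- TRUE                                     # 5 FP
  m2 <- evaluate_mask(pred, truth)
  expect_identical(c(m2$tp, m2$fn, m2$fp, m2$tn), c(90L, 10L, 5L, 895L))
  expect_equal(m2$tdr_pct, 90)
  expect_equal(m2$fpr_pct, 100 * 5 / 900)
  expect_equal(m2$er_pct, 1.5)

  ## complement prediction: TDR 0
  expect_equal(evaluate_mask(!truth, truth)$tdr_pct, 0)

  ## partition invariants
  expect_identical(m2$tp + m2$fn, sum(truth))
  expect_identical(m2$fp + m2$tn, sum(!truth))
  expect_error(evaluate_mask(truth, matrix(TRUE, 2, 2)), "differ")
})

test_that("zero denominators are reported as 0 with a warning", {
  t0 <- matrix(FALSE, 10, 10)
  expect_warning(m <- evaluate_mask(t0, t0), "TDR")
  expect_identical(m$tdr_pct, 0)
})

test_that("the pipeline commutes with translation away from borders", {
  s <- generate_sample(synth_spec(seed = 5))
  d <- 5L
  H <- dim(s$image)[1]; W <- dim(s$image)[2]
  ri <- c(d:1, 1:(H - d)); ci <- c(d:1, 1:(W - d))
  shifted <- s$image[ri, ci, , drop = FALSE]
  m1 <- segment_image(s$image)$lesion_mask
  m2 <- segment_image(shifted)$lesion_mask
  a <- m1[1:(H - 2 * d), 1:(W - 2 * d)]
  b <- m2[(d + 1):(H - d), (d + 1):(W - d)]
  expect_gt(dice_coef(a, b), 0.99)
})
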