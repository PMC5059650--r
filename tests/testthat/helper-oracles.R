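# Independent oracles used by the unit and acceptance tests. These
# implement definitions directly (naive convolution, per-pixel sorting,
# fixed-point geodesic dilation, brute-force histograms) and share no
# code with the package internals they check.

# Mirror padding including the edge pixel (same convention the package
# documents for its borders), written with explicit index arithmetic.
oracle_pad_reflect <- function(m, pad) {
  H <- nrow(m); W <- ncol(m)
  ref <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H + 2 * pad, W + 2 * pad)
  for (i in seq_len(H + 2 * pad))
    for (j in seq_len(W + 2 * pad))
      out[i, j] <- m[ref(i - pad, H), ref(j - pad, W)]
  out
}

# Direct 2-D convolution: out(i,j) = sum_{a,b} K(a,b) * m(i - a + c, j - b + c)
# on a reflect-padded image, accumulated offset by offset.
oracle_conv2 <- function(m, kernel) {
  kh <- (nrow(kernel) - 1L) / 2L
  p <- oracle_pad_reflect(m, kh)
  H <- nrow(m); W <- ncol(m)
  acc <- matrix(0 + 0i, H, W)
  n <- nrow(kernel)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      da <- a - kh - 1L; db <- b - kh - 1L
      acc <- acc + kernel[a, b] * p[(1:H) - da + kh, (1:W) - db + kh]
    }
  }
  acc
}

# Brute-force orientation-maximum Gabor bank.
oracle_gabor_bank <- function(L, params) {
  thetas <- seq(0, 180 - params$theta_step_deg, by = params$theta_step_deg)
  inv <- 1 - L
  best <- matrix(-Inf, nrow(L), ncol(L))
  arg <- matrix(0, nrow(L), ncol(L))
  for (th in thetas) {
    k <- build_gabor_kernel(params, th)
    m <- Mod(oracle_conv2(inv, k))
    sel <- m > best
    best[sel] <- m[sel]
    arg[sel] <- th
  }
  list(response = best, argmax_theta = arg)
}

# Brute-force modal-bin cut-off on a 2^b-bin histogram over [0, 1].
oracle_cutoff <- function(x, b_bits = 4L, scale_p = 0.88) {
  nb <- 2L^b_bits
  counts <- integer(nb)
  for (v in as.numeric(x)) {
    i <- min(floor(v * nb), nb - 1L)
    counts[i + 1L] <- counts[i + 1L] + 1L
  }
  istar <- max(which(counts == max(counts))) - 1L
  scale_p * (istar + 0.5) / nb
}

# Per-pixel sorted median over a disk footprint, reflective borders.
oracle_median_disk <- function(m, radius) {
  H <- nrow(m); W <- ncol(m)
  p <- oracle_pad_reflect(m, radius)
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  out <- matrix(0, H, W)
  for (i in seq_len(H))
    for (j in seq_len(W))
      out[i, j] <- stats::median(p[cbind(i + radius + offs$a,
                                         j + radius + offs$b)])
  out
}

# Fixed-point geodesic dilation: marker <- pmin(dilate3x3(marker), mask)
# until stable (the definition of reconstruction by dilation, 8-conn).
oracle_reconstruct <- function(marker, mask) {
  dil3 <- function(m) {
    H <- nrow(m); W <- ncol(m)
    p <- matrix(-Inf, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- m
    out <- m
    for (da in -1:1)
      for (db in -1:1)
        out <- pmax(out, p[(2:(H + 1)) + da, (2:(W + 1)) + db])
    out
  }
  cur <- marker
  repeat {
    nxt <- pmin(dil3(cur), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# Brute-force solidity: convex hull of pixel-square corners, pixel
# centres inside or on the hull.
oracle_solidity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  corners <- cbind(c(r - .5, r - .5, r + .5, r + .5),
                   c(c - .5, c + .5, c - .5, c + .5))
  h <- grDevices::chull(corners)
  grid <- expand.grid(r = min(r):max(r), c = min(c):max(c))
  inside <- pracma::inpolygon(grid$r, grid$c,
                              corners[h, 1], corners[h, 2], boundary = TRUE)
  nrow(idx) / max(sum(inside), nrow(idx))
}

# Textbook sRGB (D65/2 deg) -> CIELAB L* for one gray value in [0, 1].
oracle_gray_Lstar <- function(v) {
  lin <- if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
  y <- lin                               # for gray, Y = linear value
  f <- if (y > (6 / 29)^3) y^(1 / 3) else y * (29 / 6)^2 / 3 + 4 / 29
  116 * f - 16
}

dice_coef <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Small convenience fixture: bimodal luminance field.
bimodal_map <- function(H = 32, W = 32, lo = 0.2, hi = 0.9, frac_hi = 0.7,
                        seed = 1) {
  set.seed(seed)
  m <- matrix(lo, H, W)
  m[sample.int(H * W, round(frac_hi * H * W))] <- hi
  m
}
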