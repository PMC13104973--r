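# Shared numeric helpers: seeded evaluation, Gaussian smoothing, Otsu
# thresholds, linear resampling and small mask utilities.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 2D or 3D array with reflect padding.
gauss_smooth <- function(a, sigma, truncate = 4) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  nd <- length(d)
  k <- gaussian_kernel_1d(sigma, truncate)
  if (is.null(d)) stop("`a` must be an array")
  perm <- if (nd == 2L) c(2L, 1L) else c(2L, 3L, 1L)
  for (i in seq_len(nd)) {
    a <- cpp_conv1_reflect(a, k)
    a <- aperm(a, perm)
  }
  a
}

# Single Otsu threshold of a numeric vector/array, delegated to EBImage.
# Returns a threshold on the data's own intensity scale.
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  m <- matrix(v, nrow = 1L)
  EBImage::otsu(EBImage::Image(m), range = rng, levels = levels)
}

# Two-threshold (3-class) Otsu: maximizes between-class variance over all
# bin pairs of a 256-bin histogram. Returns c(lower, upper) thresholds.
otsu_two_thresholds <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) <= 0) stop("cannot compute multi-level Otsu of a constant image")
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), levels),
                nbins = levels)
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  p <- h / sum(h)
  cp <- cumsum(p)
  cm <- cumsum(p * mids)
  total_mean <- cm[levels]
  best <- -Inf
  best_ij <- c(1L, 2L)
  for (i in seq_len(levels - 2L)) {
    w0 <- cp[i]
    if (w0 <= 0) next
    m0 <- cm[i] / w0
    for (j in (i + 1L):(levels - 1L)) {
      w1 <- cp[j] - cp[i]
      w2 <- 1 - cp[j]
      if (w1 <= 0 || w2 <= 0) next
      m1 <- (cm[j] - cm[i]) / w1
      m2 <- (total_mean - cm[j]) / w2
      v_b <- w0 * (m0 - total_mean)^2 + w1 * (m1 - total_mean)^2 +
        w2 * (m2 - total_mean)^2
      if (v_b > best) {
        best <- v_b
        best_ij <- c(i, j)
      }
    }
  }
  c(br[best_ij[1] + 1L], br[best_ij[2] + 1L])
}

# Linear resampling of a 3D array along its first axis to `n_new` samples,
# endpoints aligned (a linear ramp is reproduced exactly).
resample_axis1 <- function(a, n_new) {
  d <- dim(a)
  n <- d[1]
  if (n_new == n) return(a)
  if (n == 1L) {
    out <- array(rep(a, each = n_new), dim = c(n_new, d[-1]))
    return(out)
  }
  pos <- seq(1, n, length.out = n_new)
  lo <- pmax(1L, pmin(n - 1L, floor(pos)))
  w <- pos - lo
  m <- matrix(a, nrow = n)
  out <- m[lo, , drop = FALSE] * (1 - w) + m[lo + 1L, , drop = FALSE] * w
  array(out, dim = c(n_new, d[-1]))
}

resample_volume_linear <- function(a, new_dim) {
  a <- resample_axis1(a, new_dim[1])
  a <- aperm(a, c(2, 3, 1))                     # Y X Z
  a <- resample_axis1(a, new_dim[2])
  a <- aperm(a, c(2, 3, 1))                     # X Z Y
  a <- resample_axis1(a, new_dim[3])
  aperm(a, c(2, 3, 1))                          # Z Y X
}

# Nearest-neighbour resampling of a 3D logical mask to `new_dim`.
resample_mask_nn <- function(mask, new_dim) {
  d <- dim(mask)
  idx1 <- pmin(d[1], pmax(1L, round(seq(1, d[1], length.out = new_dim[1]))))
  idx2 <- pmin(d[2], pmax(1L, round(seq(1, d[2], length.out = new_dim[2]))))
  idx3 <- pmin(d[3], pmax(1L, round(seq(1, d[3], length.out = new_dim[3]))))
  mask[idx1, idx2, idx3, drop = FALSE]
}

# Offsets (0-based, n x 3) of a discrete Euclidean ball of radius r.
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(i = (-r):r, j = (-r):r, k = (-r):r)
  keep <- g$i^2 + g$j^2 + g$k^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# Remove 2D connected components smaller than min_px (8-connectivity).
filter_small_2d <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim = dim(mask))
}

# Fill holes of a 2D mask via EBImage.
fill_holes_2d <- function(mask) {
  if (!any(mask)) return(mask)
  out <- EBImage::fillHull(EBImage::Image(mask * 1))
  array(as.numeric(out) > 0.5, dim = dim(mask))
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
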