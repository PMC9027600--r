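#' @useDynLib bpequant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx fft median qnorm quantile rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so library calls never perturb user code.
# seed = NULL runs `code` without touching the RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 1-D Gaussian smoothing matrix (n x n), truncated at 3 sigma, reflecting
# boundaries, rows renormalised to sum to 1.  sigma in voxel units.
gauss_matrix_1d <- function(n, sigma) {
  if (sigma <= 0) return(Matrix::Diagonal(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  reflect <- function(cols) {
    if (n == 1L) return(rep(1L, length(cols)))
    m <- abs(cols - 1L) %% (2L * (n - 1L))
    as.integer(1L + pmin(m, 2L * (n - 1L) - m))
  }
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (d in (-r):r) {
    rows <- seq_len(n)
    cols <- reflect(rows + d)
    i <- c(i, rows); j <- c(j, cols); x <- c(x, rep(k[d + r + 1L], n))
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  m / Matrix::rowSums(m)
}

# Separable 3-D Gaussian smoothing of an array; sigma_vox is a length-3
# vector of per-axis standard deviations in voxels.
gauss_smooth3 <- function(a, sigma_vox) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  x <- a
  if (sigma_vox[1] > 0) {
    m <- gauss_matrix_1d(d[1], sigma_vox[1])
    x <- array(as.numeric(m %*% matrix(x, d[1], d[2] * d[3])), dim = d)
  }
  if (sigma_vox[2] > 0) {
    m <- gauss_matrix_1d(d[2], sigma_vox[2])
    x <- aperm(array(as.numeric(m %*% matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])),
                     dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    m <- gauss_matrix_1d(d[3], sigma_vox[3])
    x <- aperm(array(as.numeric(m %*% matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2])),
                     dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  x
}

# Otsu's threshold on a numeric vector: maximises between-class variance of
# the binned intensity histogram.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Two-threshold (3-class) Otsu: maximises the between-class variance of a
# three-class split of the binned histogram; returns c(t1, t2).  Used where
# the histogram has background, mid and bright classes and the wanted cut
# is background/tissue — a plain binary Otsu can flip to the mid/bright
# split when class proportions shift.
otsu_thresholds2 <- function(x, nbins = 128L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  W <- cumsum(p)
  M <- cumsum(p * mids)
  cls <- function(a, b) {       # class weight/mean-sum over bins (a, b]
    w <- W[b] - if (a > 0) W[a] else 0
    m <- M[b] - if (a > 0) M[a] else 0
    if (w <= 0) return(0)
    m^2 / w
  }
  best <- c(-Inf, 1L, 2L)
  for (i in seq_len(nbins - 2L)) {
    ci <- cls(0L, i)
    for (j in seq(i + 1L, nbins - 1L)) {
      v <- ci + cls(i, j) + cls(j, nbins)
      if (v > best[1]) best <- c(v, i, j)
    }
  }
  c(mids[best[2]], mids[best[3]])
}

# Cubic B-spline basis over a uniform mesh with `n_int` intervals spanning
# [0, extent]; evaluated at positions `pos` (same units as extent).
# Returns a dense matrix length(pos) x (n_int + 3).
bspline_basis_1d <- function(pos, extent, n_int) {
  h <- extent / n_int
  knots <- seq(-3 * h, extent + 3 * h, by = h)
  pos <- pmin(pmax(pos, 0), extent * (1 - 1e-12))
  splines::splineDesign(knots, pos, ord = 4L, outer.ok = TRUE)
}

dice_raw <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
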