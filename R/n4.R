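#' N4 parameters
#'
#' Defaults follow the reference implementation's documented defaults:
#' four resolution levels of up to 50 iterations each, convergence when
#' the coefficient of variation of the inter-iteration field ratio falls
#' below 0.001, a 200-bin log-intensity histogram deconvolved by a
#' Gaussian of FWHM 0.15 (log-intensity units) with Wiener regulariser
#' 0.01, and 4x downsampling during estimation.
#'
#' @param levels number of resolution levels; the B-spline control mesh is
#'   subdivided (doubled) at each level.
#' @param max_iter_per_level iteration cap per level.
#' @param convergence_cv convergence threshold on the coefficient of
#'   variation of the per-iteration multiplicative field update.
#' @param hist_bins histogram bin count (>= 32).
#' @param bias_fwhm FWHM of the Gaussian deconvolution kernel,
#'   log-intensity units.
#' @param wiener_noise Wiener deconvolution regulariser.
#' @param spline_spacing_mm control-point spacing of the B-spline mesh at
#'   the coarsest level; `NULL` (default) uses a single cubic span over
#'   each axis at the coarsest level.
#' @param spline_penalty relative weight of the second-difference penalty
#'   on the control-point lattice in the least-squares fit (scaled by the
#'   mean diagonal of the normal matrix).  Keeps fine meshes from chasing
#'   noise when control points outnumber the downsampled voxels; smooth
#'   field components suppressed by the penalty are recovered over the
#'   iterations.
#' @param shrink_factor integer downsampling applied during estimation
#'   only; the estimated field is evaluated at full resolution.
#' @return An `n4_params` list.
#' @export
n4_params <- function(levels = 4L, max_iter_per_level = 50L,
                      convergence_cv = 0.001, hist_bins = 200L,
                      bias_fwhm = 0.15, wiener_noise = 0.01,
                      spline_spacing_mm = NULL, spline_penalty = 1,
                      shrink_factor = 4L) {
  stopifnot(levels >= 1L, max_iter_per_level >= 1L, hist_bins >= 32L,
            bias_fwhm > 0, wiener_noise > 0, shrink_factor >= 1L,
            spline_penalty >= 0)
  structure(list(levels = as.integer(levels),
                 max_iter_per_level = as.integer(max_iter_per_level),
                 convergence_cv = convergence_cv,
                 hist_bins = as.integer(hist_bins),
                 bias_fwhm = bias_fwhm, wiener_noise = wiener_noise,
                 spline_spacing_mm = spline_spacing_mm,
                 spline_penalty = spline_penalty,
                 shrink_factor = as.integer(shrink_factor)),
            class = "n4_params")
}

# Second-difference (P-spline) penalty over a 3-D control lattice:
# sum over axes of the squared second differences of coefficients.
lattice_penalty <- function(nc) {
  pen1 <- lapply(nc, function(m) {
    if (m > 2)
      Matrix::crossprod(Matrix::Matrix(diff(diag(m), differences = 2), sparse = TRUE))
    else Matrix::Diagonal(m) * 0
  })
  I <- lapply(nc, Matrix::Diagonal)
  Matrix::kronecker(pen1[[3]], Matrix::kronecker(I[[2]], I[[1]])) +
    Matrix::kronecker(I[[3]], Matrix::kronecker(pen1[[2]], I[[1]])) +
    Matrix::kronecker(I[[3]], Matrix::kronecker(I[[2]], pen1[[1]]))
}

#' Estimated bias field
#'
#' @param log_field 3-D array: log of the multiplicative field on the full
#'   grid (extended smoothly outside the mask by the B-spline model).
#' @param spacing voxel spacing in mm.
#' @param mask_ref optional `binary_mask` used for estimation.
#' @return A `bias_field_estimate` object.
#' @export
bias_field <- function(log_field, spacing, mask_ref = NULL) {
  stopifnot(length(dim(log_field)) == 3L, all(is.finite(log_field)))
  structure(list(log_field = log_field, spacing = as.numeric(spacing),
                 mask_ref = mask_ref),
            class = "bias_field_estimate")
}

# Histogram-sharpening remap: returns for each log intensity u its
# conditional expectation under the Wiener-deconvolved ("sharpened")
# intensity distribution.  This is the E-step of the N4 iteration: the
# histogram of current log intensities is deconvolved by a Gaussian of the
# given FWHM, and each voxel is remapped to the expected uncorrupted
# intensity given its observed value.
sharpen_remap <- function(u, bins, fwhm, wiener) {
  rng <- range(u)
  if (diff(rng) <= 0) return(u)
  binw <- diff(rng) / (bins - 1)
  centers <- seq(rng[1], rng[2], length.out = bins)
  # linear (triangular) binning for a smooth histogram
  pos <- (u - rng[1]) / binw + 1
  i0 <- pmin(floor(pos), bins)
  frac <- pos - i0
  g <- c(i0, i0 + 1)
  w <- c(1 - frac, frac)
  hs <- rowsum(w, g)
  h <- numeric(bins + 1)
  h[as.integer(rownames(hs))] <- hs[, 1]
  h <- h[seq_len(bins)]

  sig <- (fwhm / (2 * sqrt(2 * log(2)))) / binw
  # centre the histogram in the padded array (pad wide enough for the
  # kernel support) so circular convolution cannot wrap data onto itself
  P <- 2^ceiling(log2(max(2 * bins, bins + 8 * sig)))
  off <- (P - bins) %/% 2
  hp <- numeric(P)
  hp[off + seq_len(bins)] <- h
  x <- c(0:(P / 2), seq(-P / 2 + 1, -1))
  gk <- exp(-x^2 / (2 * sig^2))
  gk <- gk / sum(gk)
  Gf <- fft(gk)
  # Wiener deconvolution of the histogram
  Ff <- Conj(Gf) / (Mod(Gf)^2 + wiener) * fft(hp)
  f <- pmax(Re(fft(Ff, inverse = TRUE)) / P, 0)
  # conditional expectation E[true | observed] under the sharpened
  # density; bin locations continue linearly through the padding
  cpad <- (seq_len(P) - off - 1) * binw + rng[1]
  num <- Re(fft(fft(f * cpad) * Gf, inverse = TRUE)) / P
  den <- Re(fft(fft(f) * Gf, inverse = TRUE)) / P
  mapv <- (num / pmax(den, 1e-30))[off + seq_len(bins)]
  approx(centers, mapv, xout = u, rule = 2)$y
}

# Sparse tensor-product cubic B-spline design matrix at scattered voxels.
# iv, jv, kv: 1-based shrunk-grid indices of the voxels; B1, B2, B3 dense
# per-axis basis matrices; j01/j02/j03 the first support column per grid
# position along each axis.
spline_design_scattered <- function(iv, jv, kv, B1, B2, B3, j01, j02, j03) {
  n <- length(iv)
  nc1 <- ncol(B1); nc2 <- ncol(B2); nc3 <- ncol(B3)
  s1 <- j01[iv]; s2 <- j02[jv]; s3 <- j03[kv]
  v1 <- sapply(0:3, function(o) B1[cbind(iv, s1 + o)])
  v2 <- sapply(0:3, function(o) B2[cbind(jv, s2 + o)])
  v3 <- sapply(0:3, function(o) B3[cbind(kv, s3 + o)])
  if (n == 1L) { v1 <- rbind(v1); v2 <- rbind(v2); v3 <- rbind(v3) }
  cols <- matrix(0L, n, 64L)
  vals <- matrix(0, n, 64L)
  t <- 0L
  for (r in 1:4) for (q in 1:4) for (p in 1:4) {
    t <- t + 1L
    cols[, t] <- (s3 + r - 2L) * nc1 * nc2 + (s2 + q - 2L) * nc1 + (s1 + p - 1L)
    vals[, t] <- v1[, p] * v2[, q] * v3[, r]
  }
  Matrix::sparseMatrix(i = rep(seq_len(n), 64L), j = as.integer(cols),
                       x = as.numeric(vals), dims = c(n, nc1 * nc2 * nc3))
}

first_support <- function(pos, extent, n_int) {
  h <- extent / n_int
  pmin(pmax(findInterval(pos, seq(0, extent, by = h), rightmost.closed = TRUE),
            1L), n_int)
}

# Evaluate a tensor-product spline coefficient array on the full grid.
eval_tensor_field <- function(coefs, B1, B2, B3) {
  nc <- dim(coefs)
  d1 <- nrow(B1); d2 <- nrow(B2); d3 <- nrow(B3)
  t1 <- B1 %*% matrix(coefs, nc[1], nc[2] * nc[3])          # d1 x (nc2 nc3)
  t1 <- array(as.numeric(t1), c(d1, nc[2], nc[3]))
  t2 <- B2 %*% matrix(aperm(t1, c(2, 1, 3)), nc[2], d1 * nc[3])
  t2 <- aperm(array(as.numeric(t2), c(d2, d1, nc[3])), c(2, 1, 3))  # d1 d2 nc3
  t3 <- B3 %*% matrix(aperm(t2, c(3, 1, 2)), nc[3], d1 * d2)
  aperm(array(as.numeric(t3), c(d3, d1, d2)), c(2, 3, 1))
}

#' N4 bias-field estimation and correction within a mask
#'
#' Estimates the low-frequency multiplicative bias field of an MR volume
#' from the voxels inside `mask` and divides it out.  The algorithm works
#' in log-intensity space and iterates: (a) build the log-intensity
#' histogram; (b) sharpen it by Wiener deconvolution with a Gaussian of
#' FWHM `bias_fwhm`; (c) remap each voxel to its sharpened-histogram
#' conditional expectation; (d) fit the residual (current log intensity
#' minus remapped value) with a least-squares tensor cubic B-spline on the
#' control mesh; (e) add the fitted increment to the accumulated log
#' field.  A level converges when the coefficient of variation of the
#' multiplicative update over the mask falls below `convergence_cv`;
#' successive levels subdivide the control mesh.  Estimation runs on a
#' `shrink_factor`-downsampled grid; the final field is evaluated
#' analytically at full resolution and normalised to zero mean log over
#' the estimation mask.
#'
#' Voxels outside the mask never influence the estimate; nonpositive
#' voxels inside the mask are excluded from estimation but receive the
#' interpolated field.
#'
#' @param volume `study_volume` to correct (typically pre-contrast S0).
#' @param mask `binary_mask` restricting estimation (whole-breast mask).
#' @param params an [n4_params()] object.
#' @return List with `corrected` (a `study_volume`), `field` (a
#'   `bias_field_estimate`) and `diagnostics` (per-level iteration counts
#'   and final convergence value).
#' @export
n4_correct <- function(volume, mask, params = n4_params()) {
  stopifnot(inherits(volume, "study_volume"), inherits(mask, "binary_mask"),
            inherits(params, "n4_params"))
  assert_cohort_grid(volume, mask)
  v <- volume$data
  d <- dim(v)
  if (!any(mask$data)) stop("mask is empty")
  est_full <- mask$data & (v > 0)
  if (!any(est_full)) stop("no positive voxels inside the mask")

  # the estimation grid must sample the mask densely enough for a stable
  # fit; halve the shrink factor until it does
  s <- params$shrink_factor
  repeat {
    idx1 <- seq(1L, d[1], by = s); idx2 <- seq(1L, d[2], by = s)
    idx3 <- seq(1L, d[3], by = s)
    ms <- est_full[idx1, idx2, idx3, drop = FALSE]
    if (sum(ms) >= 1024L || s == 1L) break
    s <- max(1L, s %/% 2L)
  }
  vs <- v[idx1, idx2, idx3, drop = FALSE]
  u0 <- log(vs[ms])
  n <- length(u0)

  sp <- volume$spacing
  extent <- (d - 1) * sp
  pos_s <- list((idx1 - 1) * sp[1], (idx2 - 1) * sp[2], (idx3 - 1) * sp[3])
  midx <- which(ms, arr.ind = TRUE)

  base_int <- if (is.null(params$spline_spacing_mm)) c(1L, 1L, 1L) else
    pmax(1L, as.integer(round(extent / params$spline_spacing_mm)))

  logfield <- numeric(n)
  coef_levels <- vector("list", params$levels)
  mesh_levels <- vector("list", params$levels)
  iters <- integer(params$levels)
  cv <- NA_real_

  for (lev in seq_len(params$levels)) {
    n_int <- base_int * 2L^(lev - 1L)
    B <- lapply(1:3, function(a) bspline_basis_1d(pos_s[[a]], extent[a], n_int[a]))
    j0 <- lapply(1:3, function(a) first_support(pos_s[[a]], extent[a], n_int[a]))
    A <- spline_design_scattered(midx[, 1], midx[, 2], midx[, 3],
                                 B[[1]], B[[2]], B[[3]],
                                 j0[[1]], j0[[2]], j0[[3]])
    AtA <- Matrix::crossprod(A)
    lam <- params$spline_penalty * mean(Matrix::diag(AtA))
    ch <- Matrix::Cholesky(AtA + lam * lattice_penalty(sapply(B, ncol)) +
                             1e-8 * Matrix::Diagonal(ncol(A)), LDL = FALSE)
    coefs <- numeric(ncol(A))
    prev_cv <- Inf
    first_cv <- NA_real_
    up_streak <- 0L
    for (it in seq_len(params$max_iter_per_level)) {
      u <- u0 - logfield
      mapped <- sharpen_remap(u, params$hist_bins, params$bias_fwhm,
                              params$wiener_noise)
      resid <- u - mapped
      cf <- as.numeric(Matrix::solve(ch, Matrix::crossprod(A, resid)))
      inc <- as.numeric(A %*% cf)
      logfield <- logfield + inc
      coefs <- coefs + cf
      e <- exp(inc)
      cv <- sd(e) / mean(e)
      iters[lev] <- it
      if (is.na(cv) || cv < params$convergence_cv) break
      if (is.na(first_cv)) first_cv <- cv
      # divergence: the update keeps growing and exceeds where the level
      # started (plateaus and small oscillations are not divergence)
      if (cv > prev_cv) up_streak <- up_streak + 1L else up_streak <- 0L
      if (up_streak >= 5L && cv > 1.5 * first_cv)
        stop(sprintf("N4 diverged at level %d, iteration %d (CV rising for 5 iterations; last CV %.3g)",
                     lev, it, cv))
      prev_cv <- cv
    }
    nc <- sapply(B, ncol)
    coef_levels[[lev]] <- array(coefs, dim = nc)
    mesh_levels[[lev]] <- n_int
  }

  pos_f <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  logf_full <- array(0, dim = d)
  for (lev in seq_len(params$levels)) {
    n_int <- mesh_levels[[lev]]
    Bf <- lapply(1:3, function(a) bspline_basis_1d(pos_f[[a]], extent[a], n_int[a]))
    logf_full <- logf_full + eval_tensor_field(coef_levels[[lev]],
                                               Bf[[1]], Bf[[2]], Bf[[3]])
  }
  logf_full <- logf_full - mean(logf_full[est_full])
  corrected <- study_volume(v / exp(logf_full), sp, volume$phase_tag)
  list(corrected = corrected,
       field = bias_field(logf_full, sp, mask),
       diagnostics = list(iterations = iters, final_cv = cv,
                          shrink_used = s, mesh_levels = mesh_levels))
}

#' Apply (or remove) an estimated bias field
#'
#' Divides a volume elementwise by `exp(log_field)`; used to correct the
#' post-contrast volume S1 with the field estimated on the pre-contrast
#' volume S0.  Negating the log field inverts the operation.
#'
#' @param volume a `study_volume` on the same grid as the field.
#' @param field a `bias_field_estimate`.
#' @return The corrected `study_volume`.
#' @export
apply_field <- function(volume, field) {
  stopifnot(inherits(volume, "study_volume"),
            inherits(field, "bias_field_estimate"))
  if (!identical(dim(volume$data), dim(field$log_field)))
    stop(sprintf("grid shape mismatch: volume (%s) vs field (%s)",
                 paste(dim(volume$data), collapse = ","),
                 paste(dim(field$log_field), collapse = ",")))
  study_volume(volume$data / exp(field$log_field), volume$spacing,
               volume$phase_tag)
}
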