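#' Specify a synthetic bilateral-breast DCE phantom
#'
#' The phantom emulates a fat-suppressed T1-weighted bilateral breast
#' acquisition: two ellipsoidal breasts attached to a chest-wall slab, each
#' with a central ellipsoidal core of fibroglandular tissue (FGT) brighter
#' than the suppressed fat, imaged at a pre-contrast phase S0 and an early
#' post-contrast phase S1 in which only FGT enhances by a uniform fraction
#' `pe_true`.  A smooth multiplicative bias field (the same for both
#' phases, as coil sensitivity is contrast-independent) and additive noise
#' corrupt the observed volumes; all ground-truth masks and the injected
#' field are returned alongside.
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: fat at 100, FGT at 300 (arbitrary units, ratio ~3 as on
#' fat-suppressed T1), 30% FGT enhancement, a 1.4x peak-to-trough bias
#' field and noise at 2% of the fat intensity.
#'
#' @param grid_shape integer triple `(n_slices, n_rows, n_cols)`.
#' @param voxel_spacing mm per axis.
#' @param breast_centers list of two numeric triples (voxel coordinates of
#'   the left and right breast ellipsoid centres); `NULL` for defaults
#'   scaled to `grid_shape`.
#' @param breast_radii list of two numeric triples (ellipsoid radii in
#'   voxels); `NULL` for defaults.
#' @param chest_wall_row row index of the posterior cut plane; breasts must
#'   lie entirely anterior (lower row indices).
#' @param fgt_fraction fraction of each breast radius occupied by the
#'   central FGT ellipsoid.
#' @param intensity_fat,intensity_fgt,intensity_chest mean class signals
#'   (arbitrary units; fat < FGT mimics fat suppression).
#' @param texture_cv_fat,texture_cv_fgt coefficient of variation of the
#'   multiplicative intra-class heterogeneity (lognormal, mean-preserving,
#'   identical in S0 and S1 as a tissue property).  Real fibroglandular
#'   tissue is markedly heterogeneous; a value of 0 gives piecewise
#'   constant classes.
#' @param pe_true fractional enhancement of FGT between S0 and S1.
#' @param bias_amplitude peak-to-trough multiplicative factor of the
#'   injected bias field (1 = no bias).
#' @param bias_scale_mm spatial smoothness scale of the field.
#' @param bias_mode `"gauss"` (band-limited Gaussian random field) or
#'   `"poly"` (low-order polynomial).
#' @param noise_sigma additive noise standard deviation.
#' @param noise_model `"gaussian"` (default; signal is far above the noise
#'   floor) or `"rician"`.
#' @param tumor_side `"left"` or `"right"`: the side carrying the tumour,
#'   excluded from BPE measurement.
#' @param seed RNG seed controlling field and noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(48L, 64L, 64L),
                         voxel_spacing = c(2.5, 1.4, 1.4),
                         breast_centers = NULL,
                         breast_radii = NULL,
                         chest_wall_row = NULL,
                         fgt_fraction = 0.68,
                         intensity_fat = 100,
                         intensity_fgt = 300,
                         intensity_chest = 150,
                         texture_cv_fat = 0.05,
                         texture_cv_fgt = 0.12,
                         pe_true = 0.30,
                         bias_amplitude = 1.4,
                         bias_scale_mm = 60,
                         bias_mode = c("gauss", "poly"),
                         noise_sigma = 2,
                         noise_model = c("gaussian", "rician"),
                         tumor_side = c("left", "right"),
                         seed = 1L) {
  bias_mode <- match.arg(bias_mode)
  noise_model <- match.arg(noise_model)
  tumor_side <- match.arg(tumor_side)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  if (is.null(chest_wall_row)) chest_wall_row <- round(0.72 * grid_shape[2])
  if (is.null(breast_radii)) {
    r <- c(0.34 * grid_shape[1], 0.30 * grid_shape[2], 0.21 * grid_shape[3])
    breast_radii <- list(r, r)
  }
  if (is.null(breast_centers)) {
    cs <- (grid_shape[1] + 1) / 2
    cr <- chest_wall_row - breast_radii[[1]][2] - 1
    # column centres mirror-symmetric about the midline (1-based indices)
    breast_centers <- list(c(cs, cr, 0.27 * (grid_shape[3] + 1)),
                           c(cs, cr, 0.73 * (grid_shape[3] + 1)))
  }
  if (!(intensity_fat > 0 && intensity_fgt > 0))
    stop("class intensities must be positive")
  if (pe_true < 0) stop("pe_true must be >= 0")
  if (bias_amplitude < 1) stop("bias_amplitude must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!(fgt_fraction > 0 && fgt_fraction < 1))
    stop("fgt_fraction must lie in (0, 1)")
  if (texture_cv_fat < 0 || texture_cv_fgt < 0)
    stop("texture CVs must be >= 0")
  spec <- list(grid_shape = grid_shape, voxel_spacing = as.numeric(voxel_spacing),
               breast_centers = breast_centers, breast_radii = breast_radii,
               chest_wall_row = as.integer(chest_wall_row),
               fgt_fraction = fgt_fraction,
               intensity_fat = intensity_fat, intensity_fgt = intensity_fgt,
               intensity_chest = intensity_chest,
               texture_cv_fat = texture_cv_fat,
               texture_cv_fgt = texture_cv_fgt, pe_true = pe_true,
               bias_amplitude = bias_amplitude, bias_scale_mm = bias_scale_mm,
               bias_mode = bias_mode, noise_sigma = noise_sigma,
               noise_model = noise_model, tumor_side = tumor_side,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_geometry(spec)
  spec
}

validate_phantom_geometry <- function(spec) {
  g <- spec$grid_shape
  for (side in 1:2) {
    ce <- spec$breast_centers[[side]]
    ra <- spec$breast_radii[[side]]
    lo <- ce - ra
    hi <- ce + ra
    if (any(lo < 1) || any(hi > g))
      stop(sprintf("breast ellipsoid %d extends outside the grid (span %s..%s in a %s grid)",
                   side, paste(round(lo, 1), collapse = ","),
                   paste(round(hi, 1), collapse = ","),
                   paste(g, collapse = "x")))
    if (hi[2] >= spec$chest_wall_row)
      stop(sprintf("breast ellipsoid %d reaches row %.1f, at or posterior to chest_wall_row %d",
                   side, hi[2], spec$chest_wall_row))
  }
  invisible(spec)
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  i <- (seq_len(grid_shape[1]) - center[1]) / radii[1]
  j <- (seq_len(grid_shape[2]) - center[2]) / radii[2]
  k <- (seq_len(grid_shape[3]) - center[3]) / radii[3]
  outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
}

#' Generate a smooth multiplicative bias field
#'
#' The field emulates MR coil-sensitivity inhomogeneity: a strictly
#' positive, spatially smooth multiplicative factor.  It is constructed by
#' exponentiating a normalised smooth scalar field `g` in `[0, 1]` as
#' `bias_amplitude ^ g`, so the max/min ratio equals `bias_amplitude`
#' exactly on the generated grid.
#'
#' @param grid_shape integer triple.
#' @param bias_amplitude peak-to-trough ratio (>= 1).
#' @param bias_scale_mm smoothness scale; if it exceeds the largest grid
#'   extent the field falls back to a linear ramp, with a warning.
#' @param voxel_spacing mm per axis.
#' @param seed RNG seed.
#' @param mode `"gauss"` for an exponentiated band-limited Gaussian random
#'   field, `"poly"` for a random low-order (quadratic) polynomial field.
#' @return 3-D array, the multiplicative field (all values > 0).
#' @export
make_bias_field <- function(grid_shape, bias_amplitude, bias_scale_mm,
                            voxel_spacing, seed = 1L,
                            mode = c("gauss", "poly")) {
  mode <- match.arg(mode)
  grid_shape <- as.integer(grid_shape)
  if (bias_amplitude < 1) stop("bias_amplitude must be >= 1")
  if (bias_amplitude == 1) return(array(1, dim = grid_shape))
  extent <- grid_shape * voxel_spacing
  ramp3 <- function() {
    k <- seq(0, 1, length.out = grid_shape[3])
    array(rep(k, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
  }
  if (bias_scale_mm > max(extent)) {
    warning("bias_scale_mm exceeds the volume extent; using a linear ramp")
    g <- ramp3()
  } else if (mode == "poly") {
    co <- with_seed(seed, rnorm(10))
    i <- seq(-1, 1, length.out = grid_shape[1])
    j <- seq(-1, 1, length.out = grid_shape[2])
    k <- seq(-1, 1, length.out = grid_shape[3])
    gi <- array(rep(i, times = grid_shape[2] * grid_shape[3]), dim = grid_shape)
    gj <- array(rep(rep(j, each = grid_shape[1]), times = grid_shape[3]), dim = grid_shape)
    gk <- array(rep(k, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
    g <- co[1] + co[2] * gi + co[3] * gj + co[4] * gk +
      co[5] * gi^2 + co[6] * gj^2 + co[7] * gk^2 +
      co[8] * gi * gj + co[9] * gi * gk + co[10] * gj * gk
    g <- (g - min(g)) / (max(g) - min(g))
  } else {
    w <- with_seed(seed, array(rnorm(prod(grid_shape)), dim = grid_shape))
    sigma_vox <- (bias_scale_mm / 2) / voxel_spacing
    g <- gauss_smooth3(w, sigma_vox)
    if (max(g) - min(g) < 1e-12) {
      warning("smoothed field degenerate at this scale; using a linear ramp")
      g <- ramp3()
    } else {
      g <- (g - min(g)) / (max(g) - min(g))
    }
  }
  bias_amplitude^g
}

#' Generate a phantom exam with ground truth
#'
#' Applies the forward model `observed = clean x bias_field + noise`
#' (bias multiplies before noise, the standard coil-sensitivity model; the
#' identical field corrupts S0 and S1).  Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `bpe_phantom` with elements `s0`, `s1`
#'   (observed `study_volume`s) and `truth`, which carries `s0_clean`,
#'   `s1_clean`, `bias_field`, the ground-truth masks `breast_mask_true`,
#'   `fgt_mask_true` (both breasts), `contralateral_fgt_true`,
#'   `halfstack_mask_true` (half-stack of the contralateral FGT), and
#'   `pe_true`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_geometry(spec)
  g <- spec$grid_shape
  left <- ellipsoid_mask(g, spec$breast_centers[[1]], spec$breast_radii[[1]])
  right <- ellipsoid_mask(g, spec$breast_centers[[2]], spec$breast_radii[[2]])
  breast <- left | right
  fgt_l <- ellipsoid_mask(g, spec$breast_centers[[1]],
                          spec$breast_radii[[1]] * spec$fgt_fraction)
  fgt_r <- ellipsoid_mask(g, spec$breast_centers[[2]],
                          spec$breast_radii[[2]] * spec$fgt_fraction)
  fgt <- fgt_l | fgt_r
  slab <- array(FALSE, dim = g)
  slab_rows <- spec$chest_wall_row:min(g[2], spec$chest_wall_row + 4L)
  slab[, slab_rows, ] <- TRUE

  s0_clean <- array(0, dim = g)
  s0_clean[slab] <- spec$intensity_chest
  # mean-preserving lognormal intra-class heterogeneity, a fixed tissue
  # property shared by both phases
  tex <- with_seed(spec$seed + 2L, array(rnorm(prod(g)), dim = g))
  sf <- sqrt(log(1 + spec$texture_cv_fat^2))
  sg <- sqrt(log(1 + spec$texture_cv_fgt^2))
  s0_clean[breast] <- spec$intensity_fat * exp(sf * tex[breast] - sf^2 / 2)
  s0_clean[fgt] <- spec$intensity_fgt * exp(sg * tex[fgt] - sg^2 / 2)
  s1_clean <- s0_clean
  s1_clean[fgt] <- s0_clean[fgt] * (1 + spec$pe_true)

  field <- make_bias_field(g, spec$bias_amplitude, spec$bias_scale_mm,
                           spec$voxel_spacing, seed = spec$seed,
                           mode = spec$bias_mode)
  nvox <- prod(g)
  noise <- with_seed(spec$seed + 1L, {
    list(n0 = array(rnorm(nvox, sd = spec$noise_sigma), dim = g),
         n1 = array(rnorm(nvox, sd = spec$noise_sigma), dim = g),
         q0 = array(rnorm(nvox, sd = spec$noise_sigma), dim = g),
         q1 = array(rnorm(nvox, sd = spec$noise_sigma), dim = g))
  })
  if (spec$noise_sigma == 0) {
    s0 <- s0_clean * field
    s1 <- s1_clean * field
  } else if (spec$noise_model == "rician") {
    s0 <- sqrt((s0_clean * field + noise$n0)^2 + noise$q0^2)
    s1 <- sqrt((s1_clean * field + noise$n1)^2 + noise$q1^2)
  } else {
    s0 <- s0_clean * field + noise$n0
    s1 <- s1_clean * field + noise$n1
  }

  sp <- spec$voxel_spacing
  contra_fgt <- if (spec$tumor_side == "left") fgt_r else fgt_l
  truth <- list(
    s0_clean = s0_clean, s1_clean = s1_clean, bias_field = field,
    breast_mask_true = binary_mask(breast, sp, "breast"),
    fgt_mask_true = binary_mask(fgt, sp, "FGT"),
    left_fgt_true = binary_mask(fgt_l, sp, "FGT-left"),
    right_fgt_true = binary_mask(fgt_r, sp, "FGT-right"),
    contralateral_fgt_true = binary_mask(contra_fgt, sp, "FGT-contralateral"),
    halfstack_mask_true = half_stack(binary_mask(contra_fgt, sp, "FGT-contralateral")),
    pe_true = spec$pe_true)
  structure(list(s0 = study_volume(s0, sp, "pre"),
                 s1 = study_volume(s1, sp, "post"),
                 truth = truth, spec = spec),
            class = "bpe_phantom")
}

#' Write a phantom exam and its ground truth as NIfTI files
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "bpe_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(s0 = file.path(dir, "s0.nii.gz"), s1 = file.path(dir, "s1.nii.gz"),
         breast = file.path(dir, "breast_mask_true.nii.gz"),
         fgt = file.path(dir, "fgt_mask_true.nii.gz"),
         halfstack = file.path(dir, "halfstack_mask_true.nii.gz"),
         bias = file.path(dir, "bias_field_true.nii.gz"))
  write_volume(phantom$s0, p[["s0"]])
  write_volume(phantom$s1, p[["s1"]])
  write_mask(phantom$truth$breast_mask_true, p[["breast"]])
  write_mask(phantom$truth$fgt_mask_true, p[["fgt"]])
  write_mask(phantom$truth$halfstack_mask_true, p[["halfstack"]])
  write_volume(study_volume(phantom$truth$bias_field, phantom$spec$voxel_spacing, "pre"),
               p[["bias"]])
  invisible(p)
}
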