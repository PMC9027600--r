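#' Construct a study volume
#'
#' A study volume is a 3-D scalar image in the package's shared axis
#' convention: axis 1 indexes axial slices (superior to inferior), axis 2
#' rows (anterior to posterior), axis 3 columns (left to right).  Both
#' phases of a DCE exam — the pre-contrast volume S0 and the early
#' post-contrast volume S1 — are represented this way.
#'
#' @param data 3-D numeric array, all values finite.
#' @param spacing voxel spacing in mm, one value per axis.
#' @param phase_tag `"pre"` or `"post"`.
#' @return An object of class `study_volume` with elements `data`,
#'   `spacing` and `phase_tag`.
#' @export
study_volume <- function(data, spacing, phase_tag = c("pre", "post")) {
  phase_tag <- match.arg(phase_tag)
  if (length(dim(data)) != 3L)
    stop("study volumes must be 3-D; got dimensionality ", length(dim(data)))
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, phase_tag = phase_tag),
            class = "study_volume")
}

#' Construct a binary mask aligned to a volume grid
#'
#' @param data 3-D logical (or 0/1 numeric) array.
#' @param spacing voxel spacing in mm.
#' @param label free-text role, e.g. `"breast"`, `"FGT"`, `"half-stack"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, label = "") {
  if (length(dim(data)) != 3L)
    stop("masks must be 3-D; got dimensionality ", length(dim(data)))
  d <- dim(data)
  data <- array(as.logical(data), dim = d)
  if (anyNA(data)) stop("mask contains NA values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, label = label),
            class = "binary_mask")
}

#' @exportS3Method base::print
print.study_volume <- function(x, ...) {
  cat(sprintf("<study_volume %s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$phase_tag, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @exportS3Method base::print
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s'> %s voxels, %d foreground\n",
              x$label, paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# Canonical orientation code for the shared axis convention: axis 1
# increases toward Inferior, axis 2 toward Posterior, axis 3 toward Right.
CANONICAL_ORIENTATION <- "IPR"

canonical_xform <- function(spacing) {
  # maps voxel (i,j,k) -> world (x,y,z) under RAS world axes with the
  # canonical IPR voxel axes
  m <- matrix(0, 4, 4)
  m[3, 1] <- -spacing[1]   # i -> -z (inferior)
  m[2, 2] <- -spacing[2]   # j -> -y (posterior)
  m[1, 3] <- spacing[3]    # k -> +x (right)
  m[4, 4] <- 1
  m
}

as_canonical_nifti <- function(data, spacing) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(canonical_xform(spacing), code = 2L)
  img
}

#' Write a study volume as NIfTI
#'
#' Data are stored as float32 with the canonical orientation encoded in the
#' qform, so that [read_volume()] round-trips losslessly.
#'
#' @param vol a `study_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "study_volume"))
  img <- as_canonical_nifti(vol$data, vol$spacing)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI scalar volume into the canonical axis convention
#'
#' The on-disk orientation (qform/sform) is used to reorient the data into
#' the shared convention (axial slices superior to inferior, rows anterior
#' to posterior, columns left to right); files without any orientation
#' information are assumed to already be canonical.
#'
#' @param path path to a 3-D NIfTI file.
#' @param phase_tag phase of the volume, `"pre"` or `"post"`.
#' @return A `study_volume`.
#' @export
read_volume <- function(path, phase_tag = "pre") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop("expected a 3-D scalar volume, got ", nd, "-D data in ", path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- CANONICAL_ORIENTATION
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  study_volume(arr, spacing, phase_tag)
}

#' Write a binary mask as uint8 NIfTI (values 0/1)
#'
#' @param mask a `binary_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- as_canonical_nifti(array(as.integer(mask$data), dim = dim(mask$data)),
                            mask$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path path to a mask NIfTI (any nonzero voxel is foreground).
#' @param label role label to attach.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path, label = "") {
  vol <- read_volume(path, "pre")
  binary_mask(vol$data != 0, vol$spacing, label)
}

#' Assert that volumes and masks share one grid
#'
#' Raises an error unless every argument has the same array shape and voxel
#' spacing (spacing compared to 1e-6 mm).
#'
#' @param ... `study_volume` and/or `binary_mask` objects.
#' @return `TRUE`, invisibly.
#' @export
assert_cohort_grid <- function(...) {
  objs <- list(...)
  if (length(objs) < 2L) return(invisible(TRUE))
  ref <- objs[[1]]
  for (o in objs[-1]) {
    if (!identical(dim(o$data), dim(ref$data)))
      stop(sprintf("grid shape mismatch: (%s) vs (%s)",
                   paste(dim(ref$data), collapse = ","),
                   paste(dim(o$data), collapse = ",")))
    if (any(abs(o$spacing - ref$spacing) > 1e-6))
      stop(sprintf("voxel spacing mismatch: (%s) vs (%s) mm",
                   paste(ref$spacing, collapse = ","),
                   paste(o$spacing, collapse = ",")))
  }
  invisible(TRUE)
}
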