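#' Automatic whole-breast segmentation
#'
#' Segments both breasts from background on the pre-contrast volume and
#' restricts the result to the volume anterior to the chest wall, the
#' stand-in for the sternal-notch landmark.  The pipeline is:
#' (1) Gaussian smoothing of the coronal-plane intensities; (2)
#' foreground/background split by Otsu's threshold; (3) morphological
#' closing with a 3-voxel ball and per-slice hole filling; (4) chest-wall
#' row detection as the most posterior row at which the foreground's
#' left-right profile fuses into a single component (overridable via
#' `chest_row`); (5) retention of the two largest anterior connected
#' components.
#'
#' @param s0 pre-contrast `study_volume` in the canonical orientation.
#' @param smooth_sigma_mm isotropic smoothing scale before thresholding.
#' @param chest_row optional manual override of the posterior cut row.
#' @param closing_radius radius (voxels) of the ball used for closing.
#' @return A `breast_mask_result` list with `whole_mask`, `left_mask`,
#'   `right_mask` (`binary_mask` objects), the detected `chest_row` and
#'   `qc_flags` (character vector of warnings).
#' @export
segment_breasts <- function(s0, smooth_sigma_mm = 1.5, chest_row = NULL,
                            closing_radius = 1L) {
  stopifnot(inherits(s0, "study_volume"))
  d <- dim(s0$data)
  qc <- character(0)
  sm <- gauss_smooth3(s0$data, smooth_sigma_mm / s0$spacing)
  if (max(sm) <= 0) stop("no foreground found: volume is empty")
  # background/tissue cut from a three-class histogram split (background,
  # fat, FGT): a binary Otsu can flip to the fat/FGT boundary when the
  # background proportion shifts (e.g. on an already-masked volume)
  thr <- otsu_thresholds2(sm)[1]
  fg <- sm > thr
  if (!any(fg)) stop("no foreground found: volume is empty below threshold")
  dm <- as.integer(d)
  fg <- .cpp_binary_erode(.cpp_binary_dilate(fg, dm, closing_radius), dm, closing_radius)
  fg <- .cpp_fill_holes_slices(fg, dm)

  # chest-row detection on an eroded copy: erosion severs thin midline
  # bridges between the breasts while the chest-wall slab survives; the
  # erosion shifts the slab's anterior edge posterior by its radius,
  # which the detection compensates
  erode_r <- 2L
  fg_er <- .cpp_binary_erode(fg, dm, erode_r)
  if (any(fg_er)) {
    detected <- max(1L, detect_chest_row(fg_er) - erode_r)
  } else {
    detected <- detect_chest_row(fg)
  }
  if (is.null(chest_row)) {
    chest_row <- detected
  } else {
    chest_row <- as.integer(chest_row)
    qc <- c(qc, sprintf("chest row overridden to %d (detected %d)", chest_row, detected))
  }
  if (chest_row <= d[2]) fg[, chest_row:d[2], ] <- FALSE
  if (!any(fg)) stop("no foreground remains anterior to the chest row")

  lab <- .cpp_label_components(fg, dm)
  sizes <- tabulate(lab[lab > 0L])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
  mid <- (d[3] + 1) / 2
  if (length(keep) == 1L) {
    qc <- c(qc, "single connected component found; split at midline column")
    comp <- lab == keep[1]
    colidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
    left <- comp & colidx <= mid
    right <- comp & colidx > mid
  } else {
    m1 <- lab == keep[1]
    m2 <- lab == keep[2]
    colidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
    c1 <- mean(colidx[m1])
    c2 <- mean(colidx[m2])
    if (c1 <= c2) { left <- m1; right <- m2 } else { left <- m2; right <- m1 }
  }
  whole <- left | right
  structure(list(
    whole_mask = binary_mask(whole, s0$spacing, "breast"),
    left_mask = binary_mask(left, s0$spacing, "breast-left"),
    right_mask = binary_mask(right, s0$spacing, "breast-right"),
    chest_row = as.integer(chest_row),
    qc_flags = qc), class = "breast_mask_result")
}

# Chest-wall row heuristic: scan rows anterior -> posterior; for each row
# build the left-right presence profile (any foreground over slices) and
# count its connected runs.  The cut row is the most posterior transition
# from a multi-run (two separate breasts) to a single fused run (sternal
# region / chest wall).  If the profile never fuses, no cut is applied.
detect_chest_row <- function(fg) {
  d <- dim(fg)
  runs <- integer(d[2])
  for (r in seq_len(d[2])) {
    prof <- apply(fg[, r, , drop = FALSE], 3, any)
    runs[r] <- sum(prof & !c(FALSE, prof[-length(prof)]))
  }
  cand <- which(runs == 1L & c(0L, runs[-d[2]]) >= 2L)
  if (length(cand) == 0L) {
    last_fg <- max(c(0L, which(runs > 0L)))
    return(as.integer(min(last_fg + 1L, d[2] + 1L)))
  }
  as.integer(max(cand))
}

#' Mask of the breast contralateral to the tumour
#'
#' BPE is measured on the breast opposite the lesion so that enhancement
#' is not confounded by tumour uptake.
#'
#' @param result a `breast_mask_result` from [segment_breasts()].
#' @param tumor_side `"left"` or `"right"`.
#' @return The opposite side's `binary_mask`.
#' @export
contralateral_mask <- function(result, tumor_side = c("left", "right")) {
  tumor_side <- match.arg(tumor_side)
  stopifnot(inherits(result, "breast_mask_result"))
  m <- if (tumor_side == "left") result$right_mask else result$left_mask
  if (!any(m$data))
    stop("contralateral (", setdiff(c("left", "right"), tumor_side),
         ") breast mask is empty")
  m
}
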