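#' Fuzzy c-means parameters
#'
#' Defaults follow the study protocol for FGT segmentation: 6 clusters,
#' 20 alternating iterations, fuzziness exponent 2.0, and the two
#' highest-intensity clusters retained as fibroglandular tissue (FGT is
#' brighter than suppressed fat on fat-suppressed T1-weighted images).
#'
#' @param n_clusters cluster count (>= 2).
#' @param n_iter number of alternating membership/centroid updates.
#' @param fuzziness_m membership exponent (> 1).
#' @param tol early-stop tolerance on maximum centroid movement; 0 (the
#'   default) runs all `n_iter` iterations.
#' @param n_fgt_clusters number of highest-centroid clusters kept as FGT.
#' @param init `"quantile"` for deterministic initialisation at evenly
#'   spaced intensity quantiles (default), `"random"` for seeded random
#'   sampling of intensities.
#' @param seed RNG seed used only for `init = "random"`.
#' @return An `fcm_params` list.
#' @export
fcm_params <- function(n_clusters = 6L, n_iter = 20L, fuzziness_m = 2.0,
                       tol = 0, n_fgt_clusters = 2L,
                       init = c("quantile", "random"), seed = NULL) {
  init <- match.arg(init)
  stopifnot(n_clusters >= 2L, n_iter >= 1L, fuzziness_m > 1,
            n_fgt_clusters >= 1L, n_fgt_clusters <= n_clusters, tol >= 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 n_iter = as.integer(n_iter), fuzziness_m = fuzziness_m,
                 tol = tol, n_fgt_clusters = as.integer(n_fgt_clusters),
                 init = init, seed = seed),
            class = "fcm_params")
}

#' Fuzzy c-means segmentation of fibroglandular tissue
#'
#' Runs standard fuzzy c-means on the 1-D intensity feature of the voxels
#' inside `region` (the contralateral breast): memberships
#' `u_ik` are proportional to `(1/d_ik^2)^(1/(m-1))` normalised per voxel,
#' centroids are the `u^m`-weighted intensity means.  After the final
#' iteration each voxel is hard-assigned to its maximum-membership
#' cluster and the union of the `n_fgt_clusters` highest-centroid
#' clusters forms the FGT mask.
#'
#' Voxels coinciding exactly with a centroid receive full membership in
#' that centroid's cluster(s) (the usual zero-distance convention).
#' Duplicate initial centroids (possible on near-discrete intensity data)
#' are replaced by centroids evenly spaced over the intensity range, with
#' a warning.
#'
#' @param volume `study_volume` supplying intensities (pre-contrast S0,
#'   uncorrected or bias-corrected).
#' @param region `binary_mask` of voxels to cluster.
#' @param params an [fcm_params()] object.
#' @return An `fcm_result` list: `centroids` (ascending), `memberships`
#'   (matrix, one row per region voxel in array order, rows sum to 1),
#'   `hard` (per-voxel cluster index into the sorted centroids),
#'   `fgt_mask` (`binary_mask`), `objective_trace` (per-iteration
#'   objective values) and `fgt_clusters` (indices kept as FGT).
#' @export
fcm_segment <- function(volume, region, params = fcm_params()) {
  stopifnot(inherits(volume, "study_volume"), inherits(region, "binary_mask"),
            inherits(params, "fcm_params"))
  assert_cohort_grid(volume, region)
  x <- volume$data[region$data]
  if (length(x) == 0L) stop("region is empty")
  if (diff(range(x)) == 0) stop("region intensity is constant; cannot cluster")
  ux <- unique(x)
  if (length(ux) < params$n_clusters)
    warning(sprintf("region has only %d distinct intensities for n_clusters = %d; clusters will overlap",
                    length(ux), params$n_clusters))
  k <- params$n_clusters
  m <- params$fuzziness_m

  cent <- if (params$init == "random") {
    with_seed(params$seed, sort(sample(x, k)))
  } else {
    as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE))
  }
  if (anyDuplicated(cent)) {
    warning("duplicate initial centroids collapsed; re-spreading over the intensity range")
    cent <- seq(min(x), max(x), length.out = k)
  }

  expo <- 1 / (m - 1)
  membership_step <- function(cent) {
    d2 <- outer(x, cent, function(a, b) (a - b)^2)
    zero <- d2 < .Machine$double.eps
    inv <- (1 / pmax(d2, .Machine$double.eps))^expo
    u <- inv / rowSums(inv)
    zr <- rowSums(zero) > 0L
    if (any(zr)) {
      u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    }
    list(u = u, d2 = d2)
  }
  obj <- numeric(0)
  for (it in seq_len(params$n_iter)) {
    st <- membership_step(cent)
    um <- st$u^m
    obj <- c(obj, sum(um * st$d2))
    wsum <- colSums(um)
    new_cent <- ifelse(wsum > 0, colSums(um * x) / wsum, cent)
    shift <- max(abs(new_cent - cent))
    cent <- new_cent
    if (params$tol > 0 && shift < params$tol) break
  }
  u <- membership_step(cent)$u

  ord <- order(cent)
  cent <- cent[ord]
  u <- u[, ord, drop = FALSE]
  # ties broken toward the brighter cluster so FGT selection is stable
  hard <- max.col(u, ties.method = "last")
  fgt_clusters <- seq(k - params$n_fgt_clusters + 1L, k)
  fgt <- array(FALSE, dim = dim(region$data))
  fgt[region$data] <- hard %in% fgt_clusters
  structure(list(centroids = cent, memberships = u, hard = hard,
                 fgt_mask = binary_mask(fgt, region$spacing, "FGT"),
                 objective_trace = obj, fgt_clusters = fgt_clusters),
            class = "fcm_result")
}

#' Half-stack BPE mask
#'
#' Restricts an FGT mask to the central 50% of the axial slices that
#' contain any FGT.  With `z_first..z_last` the first and last
#' FGT-containing slices and `n` their count, the retained slices start
#' `floor(n/4)` after `z_first` and number `round(n/2)` (banker's
#' rounding; a single-slice mask is retained as-is).
#'
#' @param fgt_mask a nonempty `binary_mask`.
#' @return The restricted `binary_mask` (label `"half-stack"`).
#' @export
half_stack <- function(fgt_mask) {
  stopifnot(inherits(fgt_mask, "binary_mask"))
  z <- which(apply(fgt_mask$data, 1, any))
  if (length(z) == 0L) stop("FGT mask is empty")
  z_first <- min(z)
  z_last <- max(z)
  n <- z_last - z_first + 1L
  len <- max(1L, as.integer(round(n / 2)))
  offset <- as.integer(floor(n / 4))
  keep <- seq(z_first + offset, length.out = len)
  out <- fgt_mask$data
  drop <- setdiff(seq_len(dim(out)[1]), keep)
  out[drop, , ] <- FALSE
  binary_mask(out, fgt_mask$spacing, "half-stack")
}

#' Measure background parenchymal enhancement
#'
#' Computes the voxelwise percent enhancement
#' `PE = (S1 - S0) / S0 * 100%` and returns its arithmetic mean over the
#' mask (the BPE measurement) together with the mask voxel count.  Voxels
#' with nonpositive S0 are excluded from the mean (their count is
#' reported separately); the voxel count refers to the full mask.
#'
#' @param s0,s1 pre- and post-contrast `study_volume`s on a shared grid.
#' @param bpe_mask the half-stack `binary_mask`.
#' @param provenance `"uncorrected"` or `"bias-corrected"`, recorded in
#'   the result.
#' @param timepoint_tag free-text exam tag (e.g. `"T0"`).
#' @return A `bpe_result` list: `voxel_count`, `bpe` (%), `n_excluded`,
#'   `mask_provenance`, `timepoint_tag`.
#' @export
measure_bpe <- function(s0, s1, bpe_mask,
                        provenance = c("uncorrected", "bias-corrected"),
                        timepoint_tag = "") {
  provenance <- match.arg(provenance)
  stopifnot(inherits(s0, "study_volume"), inherits(s1, "study_volume"),
            inherits(bpe_mask, "binary_mask"))
  assert_cohort_grid(s0, s1, bpe_mask)
  msel <- bpe_mask$data
  if (!any(msel)) stop("BPE mask is empty")
  a0 <- s0$data[msel]
  a1 <- s1$data[msel]
  ok <- a0 > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    warning(sprintf("%d masked voxels with nonpositive S0 excluded from BPE", n_excluded))
  if (!any(ok)) stop("all masked voxels have nonpositive S0")
  pe <- (a1[ok] - a0[ok]) / a0[ok] * 100
  structure(list(voxel_count = sum(msel), bpe = mean(pe),
                 n_excluded = n_excluded, mask_provenance = provenance,
                 timepoint_tag = timepoint_tag),
            class = "bpe_result")
}

#' @exportS3Method base::print
print.bpe_result <- function(x, ...) {
  cat(sprintf("<bpe_result %s%s> voxel count %d, BPE %.2f%%\n",
              x$mask_provenance,
              if (nzchar(x$timepoint_tag)) paste0(" ", x$timepoint_tag) else "",
              x$voxel_count, x$bpe))
  invisible(x)
}
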