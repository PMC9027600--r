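#' Run configuration for the two-arm BPE pipeline
#'
#' @param n4 an [n4_params()] object.
#' @param fcm an [fcm_params()] object.
#' @param apply_to_post correct the post-contrast volume S1 with the field
#'   estimated on S0 (default `TRUE`); if `FALSE` the corrected arm
#'   computes PE from corrected S0 against raw S1.
#' @param smooth_sigma_mm breast-mask smoothing scale.
#' @param chest_row optional manual chest-row override.
#' @param write_overlays write axial overlay PNGs when an output directory
#'   is given.
#' @param seed seed recorded with the run (stages are deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(n4 = n4_params(), fcm = fcm_params(),
                       apply_to_post = TRUE, smooth_sigma_mm = 3,
                       chest_row = NULL, write_overlays = TRUE,
                       seed = 1L) {
  structure(list(n4 = n4, fcm = fcm, apply_to_post = apply_to_post,
                 smooth_sigma_mm = smooth_sigma_mm, chest_row = chest_row,
                 write_overlays = write_overlays, seed = as.integer(seed)),
            class = "run_config")
}

#' Run one exam through both pipeline arms
#'
#' Executes whole-breast masking once on S0, then the uncorrected arm
#' (FCM on raw S0) and the bias-corrected arm (N4 within the breast mask,
#' FCM on corrected S0) with identical downstream parameters, differing
#' only in the bias-correction stage.  Each arm clusters the
#' contralateral breast, builds the half-stack BPE mask and measures BPE;
#' percent enhancement is computed from the volumes of the same arm
#' (raw S0/S1 versus corrected S0/S1).
#'
#' @param s0,s1 pre- and post-contrast `study_volume`s on one grid.
#' @param tumor_side `"left"` or `"right"`; BPE is measured on the
#'   opposite breast.
#' @param config a [run_config()].
#' @param exam_id identifier recorded in the outputs.
#' @param timepoint_tag exam timepoint label (e.g. `"T0"`).
#' @param out_dir optional directory; when given, all intermediate masks,
#'   the estimated field, a JSON record and overlay PNGs at the
#'   half-stack centre and end slices are written there.
#' @return An `exam_result` list: `uncorrected` and `corrected`
#'   (`bpe_result`s), `record` (`comparison_record`), `masks` (half-stack
#'   masks of both arms), `breast` (the `breast_mask_result`), `field`
#'   (the `bias_field_estimate`).
#' @export
run_exam <- function(s0, s1, tumor_side, config = run_config(),
                     exam_id = "exam", timepoint_tag = "",
                     out_dir = NULL) {
  assert_cohort_grid(s0, s1)
  seg <- segment_breasts(s0, smooth_sigma_mm = config$smooth_sigma_mm,
                         chest_row = config$chest_row)
  contra <- contralateral_mask(seg, tumor_side)

  # uncorrected arm
  fcm_uc <- fcm_segment(s0, contra, config$fcm)
  hs_uc <- half_stack(fcm_uc$fgt_mask)
  res_uc <- measure_bpe(s0, s1, hs_uc, "uncorrected", timepoint_tag)

  # bias-corrected arm: field estimated on S0 within the whole-breast mask
  n4res <- n4_correct(s0, seg$whole_mask, config$n4)
  s0c <- n4res$corrected
  s1c <- if (config$apply_to_post) apply_field(s1, n4res$field) else s1
  fcm_bc <- fcm_segment(s0c, contra, config$fcm)
  hs_bc <- half_stack(fcm_bc$fgt_mask)
  res_bc <- measure_bpe(s0c, s1c, hs_bc, "bias-corrected", timepoint_tag)

  rec <- comparison_record(exam_id, res_uc, res_bc, hs_uc, hs_bc,
                           timepoint_tag = timepoint_tag)
  out <- structure(list(uncorrected = res_uc, corrected = res_bc,
                        record = rec,
                        masks = list(uncorrected = hs_uc, corrected = hs_bc),
                        breast = seg, field = n4res$field),
                   class = "exam_result")
  if (!is.null(out_dir)) write_exam_outputs(out, s0, out_dir, config)
  out
}

write_exam_outputs <- function(res, s0, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(res$breast$whole_mask, file.path(out_dir, "breast_mask.nii.gz"))
  write_mask(res$masks$uncorrected, file.path(out_dir, "bpe_mask_uncorrected.nii.gz"))
  write_mask(res$masks$corrected, file.path(out_dir, "bpe_mask_corrected.nii.gz"))
  write_volume(study_volume(exp(res$field$log_field), s0$spacing, "pre"),
               file.path(out_dir, "bias_field.nii.gz"))
  rec <- res$record
  jsonlite::write_json(
    list(exam_id = rec$exam_id, timepoint_tag = rec$timepoint_tag,
         dice = rec$dice, count_uc = rec$count_uc, count_bc = rec$count_bc,
         bpe_uc = rec$bpe_uc, bpe_bc = rec$bpe_bc,
         chest_row = res$breast$chest_row, qc_flags = res$breast$qc_flags),
    file.path(out_dir, "record.json"), auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$write_overlays)) {
    z <- which(apply(res$masks$corrected$data, 1, any))
    if (length(z) > 0) {
      slices <- unique(c(min(z), z[ceiling(length(z) / 2)], max(z)))
      for (s in slices)
        write_overlay_png(s0, res$masks$corrected, s,
                          file.path(out_dir, sprintf("overlay_slice%03d.png", s)))
    }
  }
  invisible(out_dir)
}

# Axial overlay: grayscale S0 slice with the mask blended in red.
write_overlay_png <- function(vol, mask, slice, path) {
  img <- vol$data[slice, , ]
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  m <- mask$data[slice, , ]
  rgb <- array(0, dim = c(dim(g), 3))
  rgb[, , 1] <- ifelse(m, pmin(1, 0.5 + 0.5 * g), g)
  rgb[, , 2] <- ifelse(m, 0.3 * g, g)
  rgb[, , 3] <- ifelse(m, 0.3 * g, g)
  png::writePNG(rgb, path)
  invisible(path)
}

#' Run a cohort of phantom exams through both arms
#'
#' Generates `n_exams` phantoms (differing only in seed), runs each
#' through [run_exam()], and collects per-exam comparison records.  A
#' failing exam is recorded with its error message and the run continues.
#'
#' @param n_exams number of phantom exams.
#' @param base_spec a [phantom_spec()] whose seed is offset per exam.
#' @param config a [run_config()].
#' @param out_dir optional output directory (per-exam subdirectories).
#' @return List with `records` (successful `comparison_record`s),
#'   `results` (full `exam_result`s), `failures` (named error messages).
#' @export
run_phantom_cohort <- function(n_exams, base_spec = phantom_spec(),
                               config = run_config(), out_dir = NULL) {
  records <- list()
  results <- list()
  failures <- character(0)
  for (i in seq_len(n_exams)) {
    id <- sprintf("phantom%03d", i)
    spec <- base_spec
    spec$seed <- base_spec$seed + (i - 1L) * 1000L
    res <- tryCatch({
      ph <- generate_phantom(spec)
      run_exam(ph$s0, ph$s1, spec$tumor_side, config, exam_id = id,
               out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, id))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
    } else {
      records[[id]] <- res$record
      results[[id]] <- res
    }
  }
  list(records = records, results = results, failures = failures)
}
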