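wrap_region <- function(x) {
  n <- length(x)
  d <- c(1L, 1L, n)
  list(vol = study_volume(array(x, dim = d), c(1, 1, 1)),
       region = binary_mask(array(TRUE, dim = d), c(1, 1, 1)))
}

test_that("FCM separates two well-separated intensity populations exactly", {
  set.seed(42)
  x <- c(rnorm(400, 100, 1), rnorm(300, 200, 1))
  w <- wrap_region(x)
  res <- fcm_segment(w$vol, w$region, fcm_params(n_clusters = 2, n_fgt_clusters = 1))
  expect_lt(abs(res$centroids[1] - 100), 1)
  expect_lt(abs(res$centroids[2] - 200), 1)
  expect_identical(as.vector(res$fgt_mask$data), x > 150)
  # memberships are a proper partition of unity
  expect_lt(max(abs(rowSums(res$memberships) - 1)), 1e-9)
  # alternating optimisation never increases the objective
  expect_true(all(diff(res$objective_trace) <= 1e-8))
})

test_that("FCM at study defaults recovers the phantom FGT", {
  ph <- default_phantom(noise_sigma = 0, bias_amplitude = 1)
  seg <- segment_breasts(ph$s0)
  contra <- contralateral_mask(seg, "left")
  res <- fcm_segment(ph$s0, contra)
  expect_length(res$centroids, 6L)
  expect_identical(res$fgt_clusters, 5:6)
  expect_gte(dice_score(res$fgt_mask, contra_truth(ph)), 0.95)
})

test_that("degenerate clustering inputs are handled per contract", {
  w <- wrap_region(rep(7, 100))
  expect_error(fcm_segment(w$vol, w$region), "constant")
  w2 <- wrap_region(c(rep(1, 50), rep(2, 50)))
  res <- NULL
  warns <- capture_warnings(res <- fcm_segment(w2$vol, w2$region))
  expect_match(warns, "distinct intensities", all = FALSE)
  expect_match(warns, "duplicate", all = FALSE)
  expect_true(all(is.finite(res$centroids)))
  empty <- binary_mask(array(FALSE, dim(w2$vol$data)), w2$vol$spacing)
  expect_error(fcm_segment(w2$vol, empty), "empty")
})

test_that("half-stack retains the central half of FGT-bearing slices", {
  mk <- function(slices, n_slices = 220L) {
    m <- array(FALSE, dim = c(n_slices, 3, 3))
    m[slices, 2, 2] <- TRUE
    binary_mask(m, c(1, 1, 1), "FGT")
  }
  slices_kept <- function(mask) which(apply(mask$data, 1, any))

  # a 40-slice span keeps exactly the central 20, offset 10
  hs <- half_stack(mk(11:50))
  expect_identical(slices_kept(hs), 21:40)

  # 41-slice span: banker's rounding keeps 20, same offset
  hs41 <- half_stack(mk(11:51))
  expect_identical(slices_kept(hs41), 21:40)

  # single-slice mask is retained as-is
  hs1 <- half_stack(mk(7L))
  expect_identical(slices_kept(hs1), 7L)

  # retained count = round(n/2) over all spans, and output is a subset
  for (n in 2:200) {
    hsn <- half_stack(mk(3:(n + 2)))
    kept <- slices_kept(hsn)
    expect_identical(length(kept), as.integer(max(1, round(n / 2))))
    expect_identical(kept[1], 3L + as.integer(floor(n / 4)))
  }
  expect_error(half_stack(mk(integer(0))), "empty")
})

test_that("half-stack output is always a subset of its input", {
  ph <- default_phantom()
  fgt <- contra_truth(ph)
  hs <- half_stack(fgt)
  expect_true(all(fgt$data | !hs$data))
})

test_that("BPE is the mean percent enhancement over the mask", {
  one <- function(s0, s1) {
    d <- c(1L, 1L, length(s0))
    measure_bpe(study_volume(array(s0, d), c(1, 1, 1)),
                study_volume(array(s1, d), c(1, 1, 1), "post"),
                binary_mask(array(TRUE, d), c(1, 1, 1)))
  }
  expect_equal(one(c(80, 120), c(80, 120))$bpe, 0.0)
  expect_equal(one(100, 150)$bpe, 50.0)

  # nonpositive S0 voxels are excluded but still counted in voxel_count
  expect_warning(r <- one(c(100, 0), c(150, 10)), "nonpositive")
  expect_identical(r$voxel_count, 2L)
  expect_identical(r$n_excluded, 1L)
  expect_equal(r$bpe, 50.0)

  expect_error(one(numeric(0), numeric(0)), "empty|3-D")
  expect_warning(expect_error(one(0, 1), "nonpositive"))
})

test_that("phantom BPE through truth masks equals the injected enhancement", {
  ph <- default_phantom(noise_sigma = 0, bias_amplitude = 1)
  res <- measure_bpe(ph$s0, ph$s1, ph$truth$halfstack_mask_true)
  expect_equal(res$bpe, 30.0, tolerance = 1e-9)
  expect_identical(res$voxel_count, sum(ph$truth$halfstack_mask_true$data))
})

test_that("FCM cross-checks against an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- c(rnorm(300, 100, 8), rnorm(200, 220, 15), rnorm(100, 400, 20))
  w <- wrap_region(x)
  mine <- fcm_segment(w$vol, w$region,
                      fcm_params(n_clusters = 3, n_iter = 200, tol = 1e-10,
                                 n_fgt_clusters = 1))
  ref <- e1071::cmeans(matrix(x), centers = matrix(sort(mine$centroids)),
                       iter.max = 200, m = 2)
  expect_equal(sort(mine$centroids), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
})
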