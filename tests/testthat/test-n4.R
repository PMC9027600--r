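make_masked_cube <- function(value = 50, n = c(20L, 24L, 24L)) {
  v <- study_volume(array(value, dim = n), c(2.5, 1.4, 1.4))
  m <- array(FALSE, dim = n)
  m[5:16, 6:18, 6:18] <- TRUE
  list(vol = v, mask = binary_mask(m, v$spacing, "breast"))
}

test_that("a uniform masked volume needs no correction", {
  cube <- make_masked_cube()
  res <- n4_correct(cube$vol, cube$mask)
  expect_lte(max(abs(res$field$log_field[cube$mask$data])), 1e-3)
  expect_equal(res$corrected$data[cube$mask$data],
               cube$vol$data[cube$mask$data], tolerance = 1e-3)
})

test_that("the injected phantom field is recovered and fat homogeneity improves", {
  ph <- default_phantom()
  seg <- segment_breasts(ph$s0)
  res <- n4_correct(ph$s0, seg$whole_mask)
  m <- seg$whole_mask$data
  expect_gte(cor(res$field$log_field[m], log(ph$truth$bias_field)[m]), 0.90)
  fat <- ph$truth$breast_mask_true$data & !ph$truth$fgt_mask_true$data
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(res$corrected$data[fat]), cv(ph$s0$data[fat]))
  # field normalised to zero mean log over the estimation mask
  expect_lt(abs(mean(res$field$log_field[m & ph$s0$data > 0])), 1e-9)
})

test_that("correcting twice leaves a smaller residual field", {
  ph <- default_phantom()
  seg <- segment_breasts(ph$s0)
  first <- n4_correct(ph$s0, seg$whole_mask)
  second <- n4_correct(first$corrected, seg$whole_mask)
  m <- seg$whole_mask$data
  amp <- function(f) diff(range(f$log_field[m]))
  expect_lt(amp(second$field), amp(first$field))
})

test_that("estimation is equivariant under global intensity scaling", {
  ph <- default_phantom()
  seg <- segment_breasts(ph$s0)
  res1 <- n4_correct(ph$s0, seg$whole_mask)
  scaled <- study_volume(ph$s0$data * 3.7, ph$s0$spacing, "pre")
  res2 <- n4_correct(scaled, seg$whole_mask)
  expect_equal(res2$field$log_field, res1$field$log_field, tolerance = 1e-6)
  expect_equal(res2$corrected$data, 3.7 * res1$corrected$data, tolerance = 1e-6)
})

test_that("voxels outside the mask never influence the field", {
  ph <- default_phantom()
  seg <- segment_breasts(ph$s0)
  res1 <- n4_correct(ph$s0, seg$whole_mask)
  tampered <- ph$s0
  outside <- !seg$whole_mask$data
  tampered$data[outside] <- tampered$data[outside] * 5 + 17
  res2 <- n4_correct(tampered, seg$whole_mask)
  expect_identical(res2$field$log_field, res1$field$log_field)
})

test_that("correction reduces the distance to the clean volume", {
  ph <- default_phantom(noise_sigma = 0)
  seg <- segment_breasts(ph$s0)
  res <- n4_correct(ph$s0, seg$whole_mask)
  m <- seg$whole_mask$data & ph$truth$s0_clean > 0
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lte(rmse(res$corrected$data[m], ph$truth$s0_clean[m]),
             rmse(ph$s0$data[m], ph$truth$s0_clean[m]))
})

test_that("apply_field divides the field out and inverts exactly", {
  ph <- default_phantom()
  d <- dim(ph$s0$data)
  zero <- bias_field(array(0, dim = d), ph$s0$spacing)
  expect_identical(apply_field(ph$s0, zero)$data, ph$s0$data)

  lf <- array(rnorm(prod(d), sd = 0.1), dim = d)
  fld <- bias_field(lf, ph$s0$spacing)
  neg <- bias_field(-lf, ph$s0$spacing)
  back <- apply_field(apply_field(ph$s1, fld), neg)
  expect_equal(back$data, ph$s1$data, tolerance = 1e-12)

  small <- bias_field(array(0, dim = c(2, 2, 2)), ph$s0$spacing)
  expect_error(apply_field(ph$s0, small), "mismatch")
})

test_that("degenerate masks are rejected", {
  cube <- make_masked_cube()
  empty <- binary_mask(array(FALSE, dim(cube$vol$data)), cube$vol$spacing)
  expect_error(n4_correct(cube$vol, empty), "empty")
  neg <- study_volume(array(-1, dim = dim(cube$vol$data)) + 0.0, cube$vol$spacing)
  expect_error(n4_correct(neg, cube$mask), "positive")
})
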