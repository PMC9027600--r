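test_that("noise-free, bias-free phantoms reproduce their clean volumes and PE exactly", {
  ph <- default_phantom(noise_sigma = 0, bias_amplitude = 1)
  expect_identical(ph$s0$data, ph$truth$s0_clean)
  expect_identical(ph$s1$data, ph$truth$s1_clean)

  # uniform fractional enhancement: PE formula evaluates to 100*pe_true
  fgt <- ph$truth$fgt_mask_true$data
  pe <- (ph$s1$data[fgt] - ph$s0$data[fgt]) / ph$s0$data[fgt] * 100
  expect_equal(mean(pe), 30.0, tolerance = 1e-9)
  expect_lt(max(abs(pe - 30)), 1e-9)

  # zero enhancement collapses S1 onto S0
  ph0 <- default_phantom(noise_sigma = 0, bias_amplitude = 1, pe_true = 0)
  expect_identical(ph0$s1$data, ph0$s0$data)
})

test_that("the forward model is multiplicative bias then additive noise", {
  ph <- default_phantom(noise_sigma = 0)  # bias on, noise off
  pos <- ph$truth$s0_clean > 0
  expect_equal(log(ph$s0$data[pos]) - log(ph$truth$s0_clean[pos]),
               log(ph$truth$bias_field[pos]), tolerance = 1e-12)
  # identical field on both phases
  expect_equal(log(ph$s1$data[pos]) - log(ph$truth$s1_clean[pos]),
               log(ph$truth$bias_field[pos]), tolerance = 1e-12)
  expect_true(all(ph$truth$bias_field > 0))
})

test_that("phantom generation is deterministic given the seed", {
  a <- default_phantom(seed = 7L)
  b <- default_phantom(seed = 7L)
  expect_identical(a$s0$data, b$s0$data)
  expect_identical(a$s1$data, b$s1$data)
  c <- default_phantom(seed = 8L)
  expect_false(identical(a$s0$data, c$s0$data))
})

test_that("swapping tumour side mirrors the contralateral truth masks", {
  a <- default_phantom(tumor_side = "left")
  b <- default_phantom(tumor_side = "right")
  mirrored <- b$truth$contralateral_fgt_true$data[, , rev(seq_len(dim(b$s0$data)[3]))]
  expect_identical(a$truth$contralateral_fgt_true$data, mirrored)
})

test_that("invalid geometry is rejected with a descriptive error", {
  expect_error(phantom_spec(breast_centers = list(c(24, 25, 2), c(24, 25, 48))),
               "outside the grid")
  expect_error(phantom_spec(chest_wall_row = 10L),
               "chest_wall_row|outside the grid")
  expect_error(phantom_spec(bias_amplitude = 0.9), "bias_amplitude")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
})

test_that("bias field construction honours amplitude, mode, determinism and fallback", {
  gs <- c(24L, 32L, 32L)
  sp <- c(2.5, 1.4, 1.4)
  expect_identical(make_bias_field(gs, 1, 60, sp), array(1, dim = gs))

  f_poly <- make_bias_field(gs, 1.4, 60, sp, seed = 3L, mode = "poly")
  expect_true(max(f_poly) / min(f_poly) >= 1.33 && max(f_poly) / min(f_poly) <= 1.47)

  f_gauss <- make_bias_field(gs, 1.4, 60, sp, seed = 3L)
  expect_equal(max(f_gauss) / min(f_gauss), 1.4, tolerance = 1e-9)
  expect_true(all(f_gauss > 0))

  expect_identical(make_bias_field(gs, 1.4, 60, sp, seed = 5L),
                   make_bias_field(gs, 1.4, 60, sp, seed = 5L))

  expect_warning(f_ramp <- make_bias_field(gs, 1.4, 1e5, sp, seed = 1L),
                 "linear ramp")
  expect_equal(max(f_ramp) / min(f_ramp), 1.4, tolerance = 1e-9)
})

test_that("phantom exams and truth round-trip through NIfTI output", {
  ph <- default_phantom()
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  s0 <- read_volume(paths[["s0"]])
  expect_equal(s0$data, ph$s0$data, tolerance = 1e-5)
  hs <- read_mask(paths[["halfstack"]])
  expect_identical(hs$data, ph$truth$halfstack_mask_true$data)
})
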