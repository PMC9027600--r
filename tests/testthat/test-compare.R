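mask_of <- function(v) binary_mask(array(v, dim = c(1, 1, length(v))), c(1, 1, 1))

test_that("Dice score matches its definition and conventions", {
  a <- mask_of(c(rep(TRUE, 100), rep(FALSE, 100)))
  expect_equal(dice_score(a, a), 1.0)
  b <- mask_of(c(rep(FALSE, 100), rep(TRUE, 100)))
  expect_equal(dice_score(a, b), 0.0)
  # |A| = |B| = 100 with 50 overlapping
  c1 <- mask_of(rep(c(TRUE, FALSE), each = 100))
  c2 <- mask_of(c(rep(FALSE, 50), rep(TRUE, 100), rep(FALSE, 50)))
  expect_equal(dice_score(c1, c2), 0.5)
  expect_equal(dice_score(c2, c1), 0.5)
  e <- mask_of(rep(FALSE, 10))
  expect_message(d <- dice_score(e, e), "empty")
  expect_equal(d, 1.0)
  expect_error(dice_score(a, mask_of(TRUE)), "mismatch")
})

test_that("the pseudo-median is the median Walsh average", {
  hl <- suppressWarnings(hodges_lehmann(c(1, 2, 6)))
  expect_equal(hl$pseudo_median, 2.75)
  expect_equal(hl$pseudo_median, walsh_median(c(1, 2, 6)))

  expect_equal(hodges_lehmann(rep(3.2, 8))$pseudo_median, 3.2)

  set.seed(11)
  for (i in 1:5) {
    d <- round(rnorm(sample(5:20, 1), sd = 3), 2)
    expect_equal(hodges_lehmann(d)$pseudo_median, walsh_median(d))
  }
})

test_that("Wilcoxon signed-rank p-values match full enumeration for small n", {
  expect_equal(hodges_lehmann(c(1, 2, 3, 4, 5))$p_value, 0.0625)
  set.seed(23)
  for (i in 1:10) {
    d <- rnorm(sample(4:10, 1))  # continuous: no ties, no zeros
    expect_equal(hodges_lehmann(d)$p_value, wilcoxon_p_enumerated(d),
                 tolerance = 1e-12)
  }
})

test_that("paired summaries are location-equivariant with ordered intervals", {
  set.seed(5)
  d <- rnorm(15)
  a <- hodges_lehmann(d)
  b <- hodges_lehmann(d + 4.25)
  expect_equal(b$pseudo_median, a$pseudo_median + 4.25)
  expect_equal(b$ci_low, a$ci_low + 4.25)
  expect_equal(b$ci_high, a$ci_high + 4.25)
  expect_true(a$ci_low <= a$pseudo_median && a$pseudo_median <= a$ci_high)
})

test_that("degenerate difference vectors follow the documented conventions", {
  expect_error(hodges_lehmann(numeric(0)), "no paired")
  expect_warning(r <- hodges_lehmann(rep(0, 6)), "zero")
  expect_equal(r$p_value, 1.0)
  # ties fall back to the midrank normal approximation
  rt <- hodges_lehmann(c(1, 1, 2, 2, 3, 3, -1, -2, 4, 4))
  expect_identical(rt$method, "normal-approximation")
  expect_true(rt$p_value > 0 && rt$p_value < 1)
  rp <- hodges_lehmann(c(0, 0, 1, 2, 3, -1, 2, 2), zero_method = "pratt")
  expect_true(rp$p_value > 0 && rp$p_value <= 1)
})

test_that("signed-rank results agree with stats::wilcox.test", {
  set.seed(31)
  d <- rnorm(12)
  mine <- hodges_lehmann(d)
  ref <- wilcox.test(d, conf.int = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(mine$pseudo_median, unname(ref$estimate), tolerance = 1e-9)
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-9)
})

test_that("the blinded-assessment translation reproduces all ten label collations", {
  # uncorrected mask labelled A (bias-corrected is B)
  expect_identical(translate_category("A >> B", "A"), -2L)
  expect_identical(translate_category("A > B",  "A"), -1L)
  expect_identical(translate_category("A = B",  "A"),  0L)
  expect_identical(translate_category("A < B",  "A"),  1L)
  expect_identical(translate_category("A << B", "A"),  2L)
  # uncorrected mask labelled B (bias-corrected is A)
  expect_identical(translate_category("A >> B", "B"),  2L)
  expect_identical(translate_category("A > B",  "B"),  1L)
  expect_identical(translate_category("A = B",  "B"),  0L)
  expect_identical(translate_category("A < B",  "B"), -1L)
  expect_identical(translate_category("A << B", "B"), -2L)
})

test_that("swapping the blinded labels negates every non-equal category", {
  for (a in c("A >> B", "A > B", "A = B", "A < B", "A << B"))
    expect_identical(translate_category(a, "A"), -translate_category(a, "B"))
  expect_error(translate_category("A ~ B", "A"), "invalid")
  expect_error(translate_category("A > B", "C"), "label_uc")
})

test_that("weighted kappa matches direct evaluation and its boundary cases", {
  set.seed(2)
  r1 <- sample(-2:2, 60, replace = TRUE)
  expect_equal(weighted_kappa(r1, r1)$kappa, 1.0)

  # fixed 3-category contingency example, both weightings, against the
  # independent brute-force evaluation
  a <- c(rep(1, 20), rep(2, 25), rep(3, 15), rep(1, 5), rep(2, 5), rep(3, 5))
  b <- c(rep(1, 18), rep(2, 20), rep(3, 12), rep(2, 7), rep(3, 10), rep(1, 8))
  for (w in c("linear", "quadratic")) {
    got <- weighted_kappa(a, b, weights = w, categories = 1:3)
    expect_equal(got$kappa,
                 kappa_direct(a, b, 1:3, quadratic = (w == "quadratic")),
                 tolerance = 1e-12)
    expect_true(got$ci_low <= got$kappa && got$kappa <= got$ci_high)
  }

  # independent raters: chance-corrected agreement tends to zero
  set.seed(77)
  u1 <- sample(-2:2, 1e5, replace = TRUE)
  u2 <- sample(-2:2, 1e5, replace = TRUE)
  expect_lt(abs(weighted_kappa(u1, u2)$kappa), 0.01)

  expect_warning(nk <- weighted_kappa(rep(1L, 10), sample(-2:2, 10, replace = TRUE)),
                 "single category")
  expect_true(is.nan(nk$kappa))
  expect_error(weighted_kappa(1:3, 1:4), "length")
  expect_error(weighted_kappa(c(1, 5), c(1, 2)), "category set")
})

test_that("comparison records aggregate into a cohort table", {
  ph <- default_phantom()
  hs <- half_stack(contra_truth(ph))
  r1 <- measure_bpe(ph$s0, ph$s1, hs, "uncorrected", "T0")
  r2 <- measure_bpe(ph$s0, ph$s1, hs, "bias-corrected", "T0")
  recs <- lapply(1:6, function(i)
    comparison_record(sprintf("e%02d", i), r1, r2, hs, hs, timepoint_tag = "T0"))
  tab <- suppressWarnings(cohort_table(recs))
  expect_identical(tab$quantity, c("voxel_count", "bpe"))
  expect_equal(tab$pseudo_median, c(0, 0))
  expect_error(comparison_record("x", r1, r2, hs, hs, category = 7L), "category")
})
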