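#' Sorensen-Dice similarity of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`.  Two empty masks score 1.0 by
#' convention (message emitted), since degenerate phantom configurations
#' can produce them.
#'
#' @param a,b `binary_mask` objects on a shared grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  assert_cohort_grid(a, b)
  sa <- sum(a$data)
  sb <- sum(b$data)
  if (sa + sb == 0L) {
    message("dice_score: both masks empty; returning 1.0 by convention")
    return(1.0)
  }
  2 * sum(a$data & b$data) / (sa + sb)
}

#' Hodges-Lehmann pseudo-median with Wilcoxon signed-rank test
#'
#' The pseudo-median of paired differences is the median of all Walsh
#' averages `(d_i + d_j)/2`, `i <= j`.  The 95% confidence interval comes
#' from the signed-rank null distribution's order statistics (exact for
#' n <= 25, normal approximation with continuity correction above), and
#' the two-sided p-value from the Wilcoxon signed-rank test: zeros
#' dropped under the default Wilcoxon convention (`zero_method =
#' "pratt"` keeps them in the ranking), midranks for ties, exact null
#' distribution for n <= 25 in the absence of ties.
#'
#' @param diffs numeric vector of paired differences.
#' @param conf_level confidence level for the interval.
#' @param zero_method `"wilcox"` (drop zero differences; default) or
#'   `"pratt"` (rank zeros, then drop their ranks).
#' @return A `paired_summary` list: `pseudo_median`, `ci_low`, `ci_high`,
#'   `p_value`, `n` (input length), `n_used` (after zero handling),
#'   `method`.
#' @export
hodges_lehmann <- function(diffs, conf_level = 0.95,
                           zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  diffs <- as.numeric(diffs)
  if (length(diffs) == 0L) stop("no paired differences supplied")
  if (anyNA(diffs)) stop("paired differences contain NA")
  n <- length(diffs)

  walsh <- outer(diffs, diffs, `+`)[upper.tri(matrix(0, n, n), diag = TRUE)] / 2
  walsh <- sort(walsh)
  pm <- median(walsh)
  M <- n * (n + 1) / 2
  alpha <- 1 - conf_level
  if (n <= 25) {
    k <- stats::qsignrank(alpha / 2, n)
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    k <- max(0, floor(mu + qnorm(alpha / 2) * sig - 0.5))
  }
  ci_low <- if (k >= 1) walsh[k] else walsh[1]
  ci_high <- if (k >= 1) walsh[M - k + 1] else walsh[M]

  if (all(diffs == 0)) {
    warning("all paired differences are zero; p-value set to 1")
    p <- 1.0
    n_used <- 0L
    method <- "degenerate"
  } else {
    if (zero_method == "wilcox") {
      d <- diffs[diffs != 0]
      r <- rank(abs(d))
    } else {
      r_all <- rank(abs(diffs))
      keep <- diffs != 0
      d <- diffs[keep]
      r <- r_all[keep]
    }
    n_used <- length(d)
    W <- sum(r[d > 0])
    ties <- any(duplicated(abs(d))) || zero_method == "pratt"
    if (!ties && n_used <= 25) {
      p <- min(1, 2 * min(stats::psignrank(W, n_used),
                          1 - stats::psignrank(W - 1, n_used)))
      method <- "exact"
    } else {
      if (zero_method == "pratt") {
        # zeros ranked with the rest, their ranks then removed from play
        nz <- sum(diffs == 0)
        N <- n
        mu <- (N * (N + 1) - nz * (nz + 1)) / 4
        sig2 <- (N * (N + 1) * (2 * N + 1) - nz * (nz + 1) * (2 * nz + 1)) / 24
      } else {
        mu <- n_used * (n_used + 1) / 4
        sig2 <- n_used * (n_used + 1) * (2 * n_used + 1) / 24
      }
      tie_tab <- table(r)
      sig2 <- sig2 - sum(tie_tab^3 - tie_tab) / 48
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal-approximation"
    }
  }
  structure(list(pseudo_median = pm, ci_low = ci_low, ci_high = ci_high,
                 p_value = p, n = n, n_used = n_used, method = method,
                 conf_level = conf_level),
            class = "paired_summary")
}

#' @exportS3Method base::print
print.paired_summary <- function(x, ...) {
  cat(sprintf("<paired_summary n=%d> pseudo-median %.4g [%.4g, %.4g], p = %.4g (%s)\n",
              x$n, x$pseudo_median, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

#' Translate a blinded A/B assessment into a signed category
#'
#' In the blinded comparative reading, the uncorrected and bias-corrected
#' BPE masks are presented as "A" and "B" in randomised order, and the
#' reader grades agreement with the observed FGT distribution on a
#' five-point scale (`A >> B`, `A > B`, `A = B`, `A < B`, `A << B`; `>>`
#' marks a substantial, grade-level difference).  Collating with which
#' mask was labelled A yields a signed category: positive when the
#' bias-corrected mask agreed better, negative when worse, magnitude 2
#' for a substantial difference.
#'
#' @param assessment one of `"A >> B"`, `"A > B"`, `"A = B"`, `"A < B"`,
#'   `"A << B"` (whitespace-insensitive).
#' @param label_uc which label the uncorrected mask carried, `"A"` or
#'   `"B"`.
#' @return Integer category in `{-2, -1, 0, 1, 2}`.
#' @export
translate_category <- function(assessment, label_uc) {
  key <- gsub("[[:space:]]", "", assessment)
  base <- c("A>>B" = -2L, "A>B" = -1L, "A=B" = 0L, "A<B" = 1L, "A<<B" = 2L)
  if (length(key) != 1L || is.na(base[key]))
    stop("invalid assessment token: ", assessment)
  if (length(label_uc) != 1L || !label_uc %in% c("A", "B"))
    stop("label_uc must be \"A\" or \"B\"")
  v <- unname(base[key])
  if (label_uc == "A") v else -v
}

#' Cohen's weighted kappa for two raters
#'
#' Agreement-weighted kappa over the fixed ordinal category set, with
#' linear (`1 - |i-j|/(k-1)`) or quadratic weights, and a 95% confidence
#' interval from the standard large-sample variance (Fleiss, Cohen and
#' Everitt).  If either rater uses a single category only, kappa is
#' undefined and `NaN` is returned with a warning.
#'
#' @param r1,r2 equal-length category sequences.
#' @param weights `"linear"` or `"quadratic"`.
#' @param categories the ordered category set; defaults to the five-point
#'   comparative-assessment scale `-2..2`.
#' @param conf_level confidence level.
#' @return List with `kappa`, `ci_low`, `ci_high`, `se`, `weights`, `n`.
#' @export
weighted_kappa <- function(r1, r2, weights = c("linear", "quadratic"),
                           categories = -2:2, conf_level = 0.95) {
  weights <- match.arg(weights)
  if (length(r1) != length(r2))
    stop("rating sequences differ in length: ", length(r1), " vs ", length(r2))
  n <- length(r1)
  if (n < 2L) stop("need at least 2 paired ratings")
  if (!all(r1 %in% categories) || !all(r2 %in% categories))
    stop("ratings outside the category set")
  if (length(unique(r1)) == 1L || length(unique(r2)) == 1L) {
    warning("a rater used a single category; weighted kappa is undefined")
    return(list(kappa = NaN, ci_low = NaN, ci_high = NaN, se = NaN,
                weights = weights, n = n))
  }
  k <- length(categories)
  f1 <- factor(r1, levels = categories)
  f2 <- factor(r2, levels = categories)
  tab <- table(f1, f2)
  p <- tab / n
  idx <- seq_len(k) - 1
  dist <- abs(outer(idx, idx, `-`)) / (k - 1)
  w <- if (weights == "linear") 1 - dist else 1 - dist^2
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  kappa <- (po - pe) / (1 - pe)
  # large-sample variance (non-null), Fleiss-Cohen-Everitt form
  wr <- as.numeric(w %*% pc)   # row-wise expected weights
  wc <- as.numeric(pr %*% w)   # column-wise expected weights
  term <- outer(wr, wc, `+`)
  ssq <- sum(p * (w - term * (1 - kappa))^2)
  var_k <- (ssq - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, ci_low = kappa - z * se, ci_high = kappa + z * se,
       se = se, weights = weights, n = n)
}

#' Build a comparison record for one exam
#'
#' Pairs the uncorrected and bias-corrected BPE results of one exam with
#' the Dice overlap of their half-stack masks and (optionally) the
#' translated reader category.
#'
#' @param exam_id identifier.
#' @param res_uc,res_bc `bpe_result`s for the uncorrected and
#'   bias-corrected arms.
#' @param mask_uc,mask_bc the two half-stack `binary_mask`s.
#' @param category optional integer in `{-2,...,2}` from
#'   [translate_category()].
#' @param timepoint_tag exam timepoint label.
#' @return A `comparison_record` (also a one-row list suitable for
#'   [cohort_table()]).
#' @export
comparison_record <- function(exam_id, res_uc, res_bc, mask_uc, mask_bc,
                              category = NA_integer_, timepoint_tag = "") {
  stopifnot(inherits(res_uc, "bpe_result"), inherits(res_bc, "bpe_result"))
  if (!is.na(category) && !category %in% (-2:2))
    stop("category must be in -2..2")
  structure(list(exam_id = exam_id, timepoint_tag = timepoint_tag,
                 dice = dice_score(mask_uc, mask_bc),
                 count_uc = res_uc$voxel_count, count_bc = res_bc$voxel_count,
                 bpe_uc = res_uc$bpe, bpe_bc = res_bc$bpe,
                 category = as.integer(category)),
            class = "comparison_record")
}

#' Cohort summary table of uncorrected vs corrected results
#'
#' Mirrors the layout of the study's cohort tables: per quantity
#' (voxel count, BPE) the median and quartiles of each arm plus the
#' Hodges-Lehmann pseudo-median of the paired difference
#' (bias-corrected minus uncorrected), its confidence interval and the
#' Wilcoxon signed-rank p-value; Dice quartiles alongside.
#'
#' @param records list of `comparison_record`s.
#' @return A `data.frame` with one row per quantity.
#' @export
cohort_table <- function(records) {
  stopifnot(length(records) >= 1L)
  get <- function(f) vapply(records, `[[`, numeric(1), f)
  q <- function(x) sprintf("%.6g [%.6g, %.6g]", median(x),
                           quantile(x, 0.25, names = FALSE),
                           quantile(x, 0.75, names = FALSE))
  row <- function(name, uc, bc) {
    hl <- hodges_lehmann(bc - uc)
    data.frame(quantity = name, uc = q(uc), bc = q(bc),
               pseudo_median = hl$pseudo_median,
               ci_low = hl$ci_low, ci_high = hl$ci_high,
               p_value = hl$p_value, stringsAsFactors = FALSE)
  }
  out <- rbind(row("voxel_count", get("count_uc"), get("count_bc")),
               row("bpe", get("bpe_uc"), get("bpe_bc")))
  dice <- get("dice")
  out$dice_summary <- q(dice)
  out
}
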