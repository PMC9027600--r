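#' Percent change in BPE between timepoints
#'
#' `(bpe_t - bpe_t0) / bpe_t0 * 100`, e.g. from pre-treatment (T0) to
#' early-treatment (T1, "dBPE1") or inter-regimen (T2, "dBPE2").
#'
#' @param bpe_t0 baseline BPE (%); must be positive.
#' @param bpe_t later-timepoint BPE (%).
#' @return Percent change (vectorised).
#' @export
delta_bpe <- function(bpe_t0, bpe_t) {
  if (any(bpe_t0 <= 0)) stop("bpe_t0 must be > 0 for percent change")
  (bpe_t - bpe_t0) / bpe_t0 * 100
}

# Ridge-penalised single-predictor logistic regression by IRLS.
# Objective: sum of negative log-likelihoods + lambda/2 * slope^2
# (intercept unpenalised).  Matches an inverse-regularisation-strength C
# on the summed-loss scale via lambda = 1/C.
ridge_logit <- function(x, y, lambda, max_iter = 50L, tol = 1e-9) {
  beta <- c(log((mean(y) + 0.01) / (1 - mean(y) + 0.01)), 0)
  X <- cbind(1, x)
  pen <- diag(c(0, lambda))
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(X %*% beta, -30), 30)
    p <- 1 / (1 + exp(-eta))
    wt <- pmax(p * (1 - p), 1e-10)
    g <- crossprod(X, y - p) - pen %*% beta
    H <- crossprod(X, X * as.numeric(wt)) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# Rank-statistic AUC with midrank tie correction.
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap out-of-sample AUC of a single-predictor logistic model
#'
#' Per bootstrap replicate, patients are resampled with replacement as the
#' training set and an L2-penalised single-predictor logistic model is fit
#' by penalised maximum likelihood; the inverse regularisation strength C
#' is chosen from `grid` by cross-validated training AUC, and performance
#' is the tie-corrected rank AUC on the out-of-bag patients.  The mean and
#' SD over replicates are reported.  Replicates whose out-of-bag set
#' contains a single class are skipped and counted; more than 50% skipped
#' is an error.
#'
#' @param predictor numeric vector (e.g. percent change in BPE).
#' @param outcome binary vector (1 = pCR, 0 = non-pCR); both classes must
#'   be present and `n >= 20`.
#' @param n_boot number of bootstrap replicates.
#' @param grid inverse regularisation strengths searched.
#' @param n_folds folds of the training-set cross-validation used for the
#'   grid search.
#' @param seed RNG seed; results are deterministic given a seed.
#' @return An `auc_summary` list: `mean_auc`, `sd_auc`, `n_boot`,
#'   `n_skipped`, `grid_chosen` (modal C and solver tag).
#' @export
bootstrap_auc <- function(predictor, outcome, n_boot = 2000L,
                          grid = c(100, 10, 1.0, 0.1, 0.01),
                          n_folds = 5L, seed = NULL) {
  x <- as.numeric(predictor)
  y <- as.integer(outcome)
  if (length(x) != length(y)) stop("predictor and outcome lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values in predictor or outcome")
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  n <- length(y)
  if (n < 20L) stop("need at least 20 patients")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")

  with_seed(seed, {
    aucs <- rep(NA_real_, n_boot)
    chosen <- rep(NA_real_, n_boot)
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) < 2L || length(unique(y[oob])) < 2L ||
          length(unique(y[idx])) < 2L) {
        skipped <- skipped + 1L
        next
      }
      xt <- x[idx]; yt <- y[idx]
      fold <- sample(rep_len(seq_len(n_folds), length(idx)))
      cv_auc <- vapply(grid, function(C) {
        av <- vapply(seq_len(n_folds), function(f) {
          tr <- fold != f
          if (length(unique(yt[tr])) < 2L || length(unique(yt[!tr])) < 2L)
            return(NA_real_)
          beta <- ridge_logit(xt[tr], yt[tr], lambda = 1 / C)
          auc_rank(beta[1] + beta[2] * xt[!tr], yt[!tr])
        }, numeric(1))
        mean(av, na.rm = TRUE)
      }, numeric(1))
      C_star <- grid[which.max(cv_auc)]
      beta <- ridge_logit(xt, yt, lambda = 1 / C_star)
      aucs[b] <- auc_rank(beta[1] + beta[2] * x[oob], y[oob])
      chosen[b] <- C_star
    }
    if (skipped > n_boot / 2)
      stop("more than half of the bootstrap replicates had a one-class out-of-bag set")
    ok <- !is.na(aucs)
    tab <- table(chosen[ok])
    structure(list(mean_auc = mean(aucs[ok]), sd_auc = sd(aucs[ok]),
                   n_boot = n_boot, n_skipped = skipped,
                   grid_chosen = list(
                     C = as.numeric(names(tab)[which.max(tab)]),
                     solver = "irls-newton")),
              class = "auc_summary")
  })
}

#' @exportS3Method base::print
print.auc_summary <- function(x, ...) {
  cat(sprintf("<auc_summary> mean AUC %.3f (SD %.3f) over %d replicates (%d skipped), modal C = %g\n",
              x$mean_auc, x$sd_auc, x$n_boot, x$n_skipped, x$grid_chosen$C))
  invisible(x)
}

#' Bootstrap AUC per predictor, provenance and subtype
#'
#' Convenience wrapper running [bootstrap_auc()] for each combination
#' present in an outcome table, optionally within immunohistochemical
#' subtype sub-groups.
#'
#' @param tbl data.frame with columns `pcr` (0/1), one column per
#'   predictor named in `predictors`, and optionally `subtype`.
#' @param predictors character vector of predictor column names.
#' @param by_subtype also analyse within each subtype level.
#' @param ... passed to [bootstrap_auc()].
#' @return data.frame with `predictor`, `subtype` (`"all"` for the full
#'   table), `mean_auc`, `sd_auc`, `n`.
#' @export
outcome_auc_table <- function(tbl, predictors, by_subtype = FALSE, ...) {
  stopifnot(is.data.frame(tbl), "pcr" %in% names(tbl),
            all(predictors %in% names(tbl)))
  groups <- list(all = seq_len(nrow(tbl)))
  if (by_subtype && "subtype" %in% names(tbl))
    for (s in unique(tbl$subtype))
      groups[[s]] <- which(tbl$subtype == s)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    do.call(rbind, lapply(predictors, function(p) {
      r <- bootstrap_auc(tbl[[p]][idx], tbl$pcr[idx], ...)
      data.frame(predictor = p, subtype = g, mean_auc = r$mean_auc,
                 sd_auc = r$sd_auc, n = length(idx),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
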