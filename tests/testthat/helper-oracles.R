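# Independent oracles used across the suite.

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of all
# 2^n sign patterns (zeros must be removed beforehand; handles ties via
# midranks).  Brute force on purpose: the implementation under test uses
# the analytic signed-rank distribution instead.
wilcoxon_p_enumerated <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  # two-sided: patterns at least as extreme (in |W - E W|) as observed
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12)
}

# Pseudo-median by explicit Walsh-average construction.
walsh_median <- function(d) {
  n <- length(d)
  w <- c()
  for (i in seq_len(n)) for (j in i:n) w <- c(w, (d[i] + d[j]) / 2)
  median(w)
}

# Weighted kappa by direct evaluation of the defining sums on a
# contingency table (independent of the package implementation).
kappa_direct <- function(r1, r2, categories, quadratic = FALSE) {
  k <- length(categories)
  n <- length(r1)
  tab <- matrix(0, k, k)
  for (t in seq_len(n)) {
    i <- match(r1[t], categories)
    j <- match(r2[t], categories)
    tab[i, j] <- tab[i, j] + 1
  }
  p <- tab / n
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- 1 - (if (quadratic) ((i - j) / (k - 1))^2 else abs(i - j) / (k - 1))
    po <- po + w * p[i, j]
    pe <- pe + w * sum(p[i, ]) * sum(p[, j])
  }
  (po - pe) / (1 - pe)
}

# Default-geometry phantom at the standard test grid.
default_phantom <- function(...) generate_phantom(phantom_spec(...))

# Restrict a truth FGT mask to the contralateral side for Dice scoring.
contra_truth <- function(ph) {
  binary_mask(ph$truth$contralateral_fgt_true$data, ph$s0$spacing, "FGT-truth")
}
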