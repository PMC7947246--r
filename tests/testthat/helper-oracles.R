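# Independent brute-force oracles used to cross-check the implementation.

# Contour-line prominence oracle: scan outward from the extremum to the
# nearest strictly higher sample (or the edge); the prominence is the drop
# to the higher of the two interval minima. Returns bases too (minimal
# sample nearest the extremum on each side).
oracle_prominence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  lmin <- h; lbase <- i
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < lmin) { lmin <- x[j]; lbase <- j }
    j <- j - 1L
  }
  rmin <- h; rbase <- i
  j <- i + 1L
  while (j <= n && x[j] <= h) {
    if (x[j] < rmin) { rmin <- x[j]; rbase <- j }
    j <- j + 1L
  }
  list(prominence = h - max(lmin, rmin), left_base = lbase, right_base = rbase)
}

# Width oracle via dense piecewise-linear resampling: evaluate the signal
# on a fine grid inside [left_base, right_base] and measure the extent of
# the region around the extremum that stays at or above the half-prominence
# level.
oracle_width <- function(x, i, res = 1e-3) {
  o <- oracle_prominence(x, i)
  level <- x[i] - o$prominence / 2
  g <- seq(o$left_base, o$right_base, by = res)
  vg <- stats::approx(seq_along(x), x, xout = g)$y
  ctr <- which.min(abs(g - i))
  above <- vg >= level - 1e-12
  lo <- ctr; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- ctr; while (hi < length(g) && above[hi + 1L]) hi <- hi + 1L
  g[hi] - g[lo]
}

# O(m*n) pairwise-kernel DeLong variance of the AUC
oracle_delong_var <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  m <- length(pos); n <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  stats::var(v10) / m + stats::var(v01) / n
}

# Exhaustive Shapley values for a single regression tree, with absent
# features marginalized cover-weighted down both branches (the same
# conditioning TreeSHAP encodes).
oracle_tree_shap <- function(tree, x) {
  f_cond <- function(node, known) {
    f <- tree$feature[node + 1L]
    if (f < 0L) return(tree$value[node + 1L])
    l <- tree$left[node + 1L]; r <- tree$right[node + 1L]
    if ((f + 1L) %in% known) {
      nxt <- if (x[f + 1L] < tree$threshold[node + 1L]) l else r
      f_cond(nxt, known)
    } else {
      (tree$cover[l + 1L] * f_cond(l, known) +
         tree$cover[r + 1L] * f_cond(r, known)) / tree$cover[node + 1L]
    }
  }
  p <- length(x)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (k in 0:length(others)) {
      combs <- utils::combn(others, k)
      if (k == 0L) combs <- matrix(integer(0), nrow = 0L, ncol = 1L)
      wt <- factorial(k) * factorial(p - k - 1L) / factorial(p)
      for (cix in seq_len(ncol(combs))) {
        S <- combs[, cix]
        phi[i] <- phi[i] + wt * (f_cond(0L, c(S, i)) - f_cond(0L, S))
      }
    }
  }
  phi
}

# band energy via the discrete Fourier transform
band_energy <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  sum(sp[freq >= f_lo & freq <= f_hi])
}
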