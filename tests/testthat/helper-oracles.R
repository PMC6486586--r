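# Independent oracles used across the suite. These re-derive quantities by
# a different route than the package implementation (power iteration,
# polynomial roots, direct formulas) so agreement is informative.

# classic weighted averaging with inverse deshrinking; the deshrinking
# regression uses sample-total weights, the convention of the WA-PLS
# iteration it is compared against
wa_inverse_oracle <- function(y, x, newdata = y) {
  u <- colSums(y * x) / colSums(y)
  wa <- as.vector(y %*% u) / rowSums(y)
  co <- stats::coef(stats::lm(x ~ wa, weights = rowSums(y)))
  wa_new <- as.vector(newdata[, names(u), drop = FALSE] %*% u) /
    rowSums(newdata[, names(u), drop = FALSE])
  as.numeric(co[1] + co[2] * wa_new)
}

# stationary distribution by power iteration
stationary_power_oracle <- function(P, iters = 10000, tol = 1e-14) {
  w <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    w2 <- as.vector(w %*% P)
    if (max(abs(w2 - w)) < tol) return(w2 / sum(w2))
    w <- w2
  }
  w / sum(w)
}

# damping ratio via the characteristic polynomial roots
damping_polyroot_oracle <- function(P) {
  k <- nrow(P)
  # characteristic polynomial coefficients from poly() of eigen is cheating;
  # build det(P - lambda I) coefficients by expanding via polyroot on the
  # monic polynomial obtained from traces (Faddeev-LeVerrier)
  cs <- numeric(k + 1); cs[1] <- 1
  M <- diag(k)
  for (i in seq_len(k)) {
    M <- P %*% M
    cs[i + 1] <- -sum(diag(M)) / i
    if (i < k) M <- M + cs[i + 1] * diag(k)
  }
  roots <- polyroot(rev(cs))
  mods <- sort(Mod(roots), decreasing = TRUE)
  if (mods[2] < 1e-12) Inf else mods[1] / mods[2]
}

# exhaustive pairwise half-L1 over row pairs
dobrushin_oracle <- function(P) {
  pairs <- utils::combn(nrow(P), 2)
  max(apply(pairs, 2, function(ij) 0.5 * sum(abs(P[ij[1], ] - P[ij[2], ]))))
}

random_stochastic <- function(k) {
  P <- matrix(stats::rexp(k * k), k, k)
  P / rowSums(P)
}

# adjusted Rand index between two hard partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# small scenario used by several test files
small_scenario <- function(seed = 5, ...) {
  scenario_preset("warming_only", n_sites = 40, years = 1991:1998,
                  seed = seed, ...)
}
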