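make_gradient_data <- function(n = 80, m = 20, seed = 1, noise = TRUE) {
  set.seed(seed)
  x <- runif(n, 5, 15)
  mu <- seq(4, 16, length.out = m)
  lam <- outer(x, mu, function(a, b) 25 * exp(-(a - b)^2 / (2 * 1.5^2)))
  y <- if (noise) matrix(rpois(n * m, lam), n, m) else lam
  colnames(y) <- sprintf("T%02d", seq_len(m))
  keep <- rowSums(y) > 0
  list(y = y[keep, , drop = FALSE], x = x[keep])
}

test_that("one-component WA-PLS equals classic WA with inverse deshrinking", {
  for (seed in 1:5) {
    d <- make_gradient_data(seed = seed)
    fit <- fit_wapls(d$y, d$x, a_max = 2)
    expect_equal(predict(fit, d$y, n_comp = 1),
                 wa_inverse_oracle(d$y, d$x), tolerance = 1e-8)
  }
})

test_that("WA-PLS predictions are faithful to training structure", {
  d <- make_gradient_data(seed = 11)
  fit <- fit_wapls(d$y, d$x, a_max = 3)
  # training set reproduces stored fitted values
  expect_equal(predict(fit, d$y), unname(fit$fitted[, fit$n_comp]),
               tolerance = 1e-10)
  # duplicated row predicts like the original
  expect_equal(predict(fit, d$y[c(3, 3), ])[1],
               predict(fit, d$y[c(3, 3), ])[2])
  # permuting taxon columns changes nothing (name-keyed alignment)
  perm <- sample(ncol(d$y))
  expect_equal(predict(fit, d$y[, perm]), predict(fit, d$y))
  # unseen taxa are ignored with a warning
  y_extra <- cbind(d$y, NEW = 5)
  expect_warning(p <- predict(fit, y_extra), "calibration")
  expect_equal(p, predict(fit, d$y))
  # constant x predicts the constant
  fitc <- fit_wapls(d$y, rep(7.5, nrow(d$y)), a_max = 2)
  expect_equal(unique(predict(fitc, d$y)), 7.5)
})

test_that("translation equivariance holds for both deshrinking conventions", {
  d <- make_gradient_data(seed = 13)
  for (dsh in c("inverse", "classical")) {
    f0 <- fit_wapls(d$y, d$x, a_max = 2, deshrink = dsh)
    f1 <- fit_wapls(d$y, d$x + 4.2, a_max = 2, deshrink = dsh)
    expect_equal(predict(f1, d$y), predict(f0, d$y) + 4.2, tolerance = 1e-8)
  }
})

test_that("classical deshrinking restores the calibration slope to one", {
  d <- make_gradient_data(seed = 17)
  f_inv <- fit_wapls(d$y, d$x, a_max = 1, deshrink = "inverse")
  f_cl <- fit_wapls(d$y, d$x, a_max = 1, deshrink = "classical")
  s_inv <- coef(lm(predict(f_inv, d$y) ~ d$x))[2]
  s_cl <- coef(lm(predict(f_cl, d$y) ~ d$x))[2]
  expect_lt(s_inv, 1)                    # inverse compresses
  expect_equal(unname(s_cl), 1, tolerance = 0.05)
})

test_that("noise-free Gaussian-response data is reconstructed faithfully", {
  d <- make_gradient_data(n = 150, m = 30, seed = 19, noise = FALSE)
  fit <- fit_wapls(d$y, d$x, a_max = 2)
  expect_gt(cor(fit$fitted[, fit$n_comp], d$x, method = "spearman"), 0.95)
  expect_gt(summary(lm(fit$fitted[, 2] ~ d$x))$r.squared, 0.9)
})

test_that("empty and degenerate inputs are handled", {
  d <- make_gradient_data(seed = 23)
  y <- d$y
  y[2, ] <- 0                            # empty sample
  expect_warning(fit <- fit_wapls(y, d$x, a_max = 1), "empty samples")
  y2 <- cbind(d$y, ZZ = 0)               # absent taxon
  expect_warning(fit_wapls(y2, d$x, a_max = 1), "absent")
  expect_error(fit_wapls(d$y, d$x[-1], a_max = 1))
  expect_error(fit_wapls(-d$y, d$x), "non-negative")
  # predicting an empty sample gives NA
  fit3 <- fit_wapls(d$y, d$x, a_max = 1)
  ynew <- d$y[1:2, ]; ynew[2, ] <- 0
  expect_warning(p <- predict(fit3, ynew), "empty")
  expect_true(is.na(p[2]) && is.finite(p[1]))
})

test_that("leave-one-out selection resists pure noise and finds 1D gradients", {
  # strong one-dimensional gradient: one component suffices
  hits <- 0
  for (seed in 1:5) {
    d <- make_gradient_data(n = 60, seed = 30 + seed)
    sel <- loo_select(d$y, d$x, a_max = 3)
    expect_gt(sel$r2[1], 0.8)
    if (sel$a == 1) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # pure-noise target: cv R-squared near zero, and the parsimony rule keeps
  # the component count at (or occasionally near) one
  stats_null <- vapply(1:5, function(seed) {
    d <- make_gradient_data(n = 40, seed = 40 + seed)
    set.seed(seed)
    sel <- loo_select(d$y, rnorm(nrow(d$y)), a_max = 3)
    c(sel$a, mean(sel$r2))
  }, c(0, 0))
  expect_gte(sum(stats_null[1, ] == 1), 3)
  expect_lt(mean(stats_null[2, ]), 0.08)
  expect_error(loo_select(make_gradient_data(n = 12)$y[1:10, ], rnorm(10)),
               "at least 20")
})

test_that("nutrient-discharge PCA composite is oriented and sized correctly", {
  set.seed(51)
  n <- 400
  base <- rnorm(n)
  x <- cbind(orthophosphate = base + rnorm(n, 0, 0.3),
             nitrate = base + rnorm(n, 0, 0.3),
             runoff = -base + rnorm(n, 0, 0.3))
  pc <- pca_composite(x, orient = "nitrate")
  expect_gt(pc$var_fraction, 0.6)
  expect_gt(cor(pc$scores, x[, "nitrate"]), 0)
  expect_gt(pc$loadings["nitrate"], 0)
  # three identical variables: PC1 explains everything
  xx <- cbind(a = base, b = base, c = base)
  expect_equal(pca_composite(xx)$var_fraction, 1)
  # three independent standard normals: fraction near 1/3
  set.seed(52)
  xi <- matrix(rnorm(3000 * 3), ncol = 3)
  expect_equal(pca_composite(xi)$var_fraction, 1 / 3, tolerance = 0.05)
  # incomplete rows get NA scores
  x[5, 1] <- NA
  expect_true(is.na(pca_composite(x)$scores[5]))
})
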