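#' Fit a weighted-averaging partial least squares (WA-PLS) transfer function
#'
#' Calibrates a model that predicts an environmental variable from community
#' composition, following the ter Braak & Juggins iteration. Each component
#' takes taxon scores as abundance-weighted averages of the current
#' environmental residuals, site scores as abundance-weighted averages of
#' those taxon scores, orthogonalises the site scores against earlier
#' components (with site-total weights), rescales them to unit weighted
#' variance, and then re-estimates the environment by a weighted regression
#' of x on all components so far (the deshrinking regression). The residuals
#' of that regression feed the next component. With one component the
#' procedure reduces to classical weighted averaging with inverse
#' deshrinking.
#'
#' @param y samples x taxa abundance matrix (log10 class midpoints or raw
#'   non-negative abundances). All-zero rows and columns are dropped with a
#'   warning.
#' @param x environmental variable, one value per sample.
#' @param a_max maximum number of components to extract; truncated with a
#'   warning if the weighted system runs out of rank.
#' @param min_occ drop taxa with fewer than this many occurrences in the
#'   calibration set before fitting (default 1 = keep all).
#' @param deshrink `"inverse"` (the weighted regression of x on the
#'   components, the convention of the core iteration) or `"classical"`
#'   (the inverse-deshrunk estimate is additionally rescaled by the inverse
#'   of its calibration regression on x, so the calibration slope of
#'   prediction on truth is exactly 1). Inverse deshrinking minimises
#'   squared prediction error but compresses reconstructions towards the
#'   calibration mean by a factor of about R-squared, which attenuates
#'   reconstructed trends; classical deshrinking preserves amplitude at the
#'   cost of a little extra variance, and is the right choice when the
#'   object of inference is a trend difference.
#' @return object of class `wapls` storing, for each component, the taxon
#'   scores, orthogonalisation and scaling constants, and the deshrinking
#'   coefficients; plus the training fitted values for every component count.
#' @export
fit_wapls <- function(y, x, a_max = 3, min_occ = 1,
                      deshrink = c("inverse", "classical")) {
  deshrink <- match.arg(deshrink)
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("taxon", seq_len(ncol(y)))
  stopifnot(nrow(y) == length(x), all(is.finite(x)))
  if (any(y < 0)) stop("abundances must be non-negative")
  occ <- colSums(y > 0)
  drop_col <- occ == 0 | occ < min_occ
  if (any(drop_col)) {
    if (any(occ == 0)) warning(sprintf("dropping %d taxa absent from all samples",
                                       sum(occ == 0)))
    y <- y[, !drop_col, drop = FALSE]
  }
  zero_row <- rowSums(y) == 0
  if (any(zero_row)) {
    warning(sprintf("dropping %d empty samples", sum(zero_row)))
    y <- y[!zero_row, , drop = FALSE]; x <- x[!zero_row]
  }
  n <- nrow(y); m <- ncol(y)
  if (a_max < 1) stop("a_max must be >= 1")
  rs <- rowSums(y); cs <- colSums(y); tot <- sum(y)
  w <- rs / tot
  xbar <- sum(rs * x) / tot
  e <- x - xbar
  u <- matrix(NA_real_, m, a_max, dimnames = list(colnames(y), NULL))
  scores <- matrix(NA_real_, n, a_max)
  ortho <- vector("list", a_max)
  scale_s <- numeric(a_max)
  beta <- vector("list", a_max)
  cl_adj <- vector("list", a_max)     # classical-deshrinking rescale (a, b)
  fitted <- matrix(NA_real_, n, a_max)
  a_used <- 0
  for (a in seq_len(a_max)) {
    u[, a] <- as.vector(crossprod(y, e)) / cs
    t_a <- as.vector(y %*% u[, a]) / rs
    f <- numeric(0)
    if (a > 1) {
      f <- vapply(seq_len(a - 1), function(b)
        sum(w * t_a * scores[, b]) / sum(w * scores[, b]^2), 0)
      t_a <- t_a - scores[, seq_len(a - 1), drop = FALSE] %*% f
      t_a <- as.vector(t_a)
    }
    s_a <- sqrt(sum(w * t_a^2))
    if (!is.finite(s_a) || s_a < 1e-10) {
      if (a == 1) {
        # x carries no weighted variance (constant): the model is the
        # weighted mean itself
        u[, 1] <- 0; scores[, 1] <- 0; ortho[[1]] <- numeric(0)
        scale_s[1] <- 1; beta[[1]] <- c(xbar, 0); cl_adj[[1]] <- c(0, 1)
        fitted[, 1] <- xbar
        a_used <- 1
        break
      }
      warning(sprintf("component %d is degenerate; truncating at %d components",
                      a, a - 1))
      break
    }
    t_a <- t_a / s_a
    scores[, a] <- t_a
    ortho[[a]] <- f
    scale_s[a] <- s_a
    reg <- stats::lm.wfit(cbind(1, scores[, seq_len(a), drop = FALSE]), x, rs)
    if (any(is.na(reg$coefficients))) {
      warning(sprintf("deshrinking regression rank-deficient; truncating at %d components",
                      a - 1))
      break
    }
    beta[[a]] <- unname(reg$coefficients)
    fit_inv <- x - reg$residuals
    if (deshrink == "classical") {
      # regress the inverse estimate on x and invert: calibration slope of
      # prediction on truth becomes exactly 1
      cl <- stats::lm.wfit(cbind(1, x), fit_inv, rs)$coefficients
      if (!is.finite(cl[2]) || abs(cl[2]) < 1e-10) cl <- c(0, 1)
      cl_adj[[a]] <- unname(cl)
      fitted[, a] <- (fit_inv - cl[1]) / cl[2]
    } else {
      cl_adj[[a]] <- c(0, 1)
      fitted[, a] <- fit_inv
    }
    e <- reg$residuals
    a_used <- a
  }
  if (a_used == 0) stop("no usable WA-PLS component could be extracted")
  structure(list(
    taxa = colnames(y), n_comp = a_used, deshrink = deshrink,
    u = u[, seq_len(a_used), drop = FALSE],
    ortho = ortho[seq_len(a_used)], scale = scale_s[seq_len(a_used)],
    beta = beta[seq_len(a_used)], cl_adj = cl_adj[seq_len(a_used)],
    xbar = xbar,
    fitted = fitted[, seq_len(a_used), drop = FALSE],
    x = x, row_weights = w
  ), class = "wapls")
}

#' Predict (reconstruct) the environment from new community samples
#'
#' Replays the stored component construction on new samples: taxa are
#' aligned to the calibration taxa by name (taxa unseen in calibration are
#' ignored with a warning; calibration taxa absent from the new table count
#' as zero abundance), site scores are formed from the stored taxon scores,
#' orthogonalised and scaled with the calibration constants, and passed
#' through the stored deshrinking regression.
#'
#' @param object fitted `wapls` model.
#' @param newdata samples x taxa matrix with taxon column names.
#' @param n_comp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of reconstructed environmental values (`NA` for
#'   empty samples).
#' @export
predict.wapls <- function(object, newdata, n_comp = object$n_comp, ...) {
  stopifnot(n_comp >= 1, n_comp <= object$n_comp)
  y <- as.matrix(newdata)
  if (is.null(colnames(y))) stop("newdata must have taxon column names")
  unseen <- setdiff(colnames(y), object$taxa)
  if (length(unseen))
    warning(sprintf("ignoring %d taxa not present in the calibration set",
                    length(unseen)))
  aligned <- matrix(0, nrow(y), length(object$taxa),
                    dimnames = list(NULL, object$taxa))
  common <- intersect(colnames(y), object$taxa)
  aligned[, common] <- y[, common]
  rs <- rowSums(aligned)
  empty <- rs == 0
  if (any(empty)) warning(sprintf("%d empty samples predicted as NA", sum(empty)))
  rs[empty] <- NA_real_
  scores <- matrix(NA_real_, nrow(y), n_comp)
  for (a in seq_len(n_comp)) {
    t_a <- as.vector(aligned %*% object$u[, a]) / rs
    if (a > 1 && length(object$ortho[[a]]))
      t_a <- t_a - as.vector(scores[, seq_len(a - 1), drop = FALSE] %*%
                               object$ortho[[a]])
    scores[, a] <- t_a / object$scale[a]
  }
  b <- object$beta[[n_comp]]
  out <- as.vector(cbind(1, scores) %*% b)
  cl <- object$cl_adj[[n_comp]]
  out <- (out - cl[1]) / cl[2]
  out[empty] <- NA_real_
  out
}

#' Leave-one-out component selection for WA-PLS
#'
#' For each candidate component count, refits the transfer function with
#' each calibration sample left out in turn and predicts the held-out
#' sample; the cross-validated R-squared is the squared correlation between
#' observations and leave-one-out predictions. The selected complexity is
#' the smallest component count whose cv R-squared is within `tol` of the
#' maximum, so extra components must earn their keep.
#'
#' @param y,x calibration data as in [fit_wapls()].
#' @param a_max maximum components considered.
#' @param tol cv R-squared tolerance of the parsimony rule (default 0.01).
#' @param min_occ,deshrink passed to [fit_wapls()].
#' @return list with `a` (selected count), `r2` (cv R-squared per count) and
#'   `pred` (n x a_max matrix of leave-one-out predictions).
#' @export
loo_select <- function(y, x, a_max = 3, tol = 0.01, min_occ = 1,
                       deshrink = "inverse") {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 20) stop("need at least 20 samples for leave-one-out selection")
  if (is.null(colnames(y))) colnames(y) <- paste0("taxon", seq_len(ncol(y)))
  pred <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    fit_i <- suppressWarnings(
      fit_wapls(y[-i, , drop = FALSE], x[-i], a_max = a_max,
                min_occ = min_occ, deshrink = deshrink))
    p <- suppressWarnings(lapply(seq_len(fit_i$n_comp), function(a)
      predict(fit_i, y[i, , drop = FALSE], n_comp = a)))
    pred[i, seq_len(fit_i$n_comp)] <- unlist(p)
  }
  r2 <- apply(pred, 2, function(p) {
    ok <- is.finite(p)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(x[ok], p[ok])^2
  })
  best <- max(r2, na.rm = TRUE)
  a_star <- min(which(r2 >= best - tol))
  list(a = a_star, r2 = r2, pred = pred)
}

#' First principal component of the nutrient-discharge complex
#'
#' Orthophosphate, nitrate and runoff are strongly intercorrelated; their
#' joint gradient is summarised by the first component of a PCA on the
#' standardised (log-transformed) variables. The component sign is fixed so
#' that PC1 correlates positively with the orienting variable (nitrate by
#' default), making outputs reproducible.
#'
#' @param x matrix or data frame of the (log) variables, one column each.
#' @param orient column name or index whose loading is forced positive.
#' @return list with `scores` (NA for incomplete rows), `var_fraction`
#'   explained by PC1, and `loadings`.
#' @export
pca_composite <- function(x, orient = 1) {
  x <- as.matrix(x)
  if (is.character(orient)) orient <- match(orient, colnames(x))
  stopifnot(is.finite(orient), orient >= 1, orient <= ncol(x))
  cc <- stats::complete.cases(x)
  if (sum(cc) < ncol(x) + 1) stop("too few complete cases for PCA")
  p <- stats::prcomp(x[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
  sgn <- if (p$rotation[orient, 1] < 0) -1 else 1
  scores <- rep(NA_real_, nrow(x))
  scores[cc] <- sgn * p$x[, 1]
  list(scores = scores,
       var_fraction = p$sdev[1]^2 / sum(p$sdev^2),
       loadings = sgn * p$rotation[, 1])
}
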