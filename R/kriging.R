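#' Local ordinary kriging with a fixed-radius neighbourhood
#'
#' Interpolates a variable observed at monitoring locations onto target
#' locations (typically biological sampling sites), using only observations
#' within `radius_km` of each target. An empirical semivariogram is computed
#' from the observations and an exponential model
#' \eqn{\gamma(h) = n + s (1 - e^{-h/a})} is fitted by weighted least
#' squares; the ordinary-kriging system is then solved per target. Ordinary
#' kriging is an exact interpolator: a target coincident with an observation
#' returns that observation's value. If the kriging system is singular the
#' prediction falls back to inverse-distance weighting with a warning.
#'
#' @param targets two-column matrix or data frame of projected target
#'   coordinates in km.
#' @param obs_xy two-column matrix of observation coordinates in km.
#' @param obs_values numeric vector of observed values.
#' @param radius_km neighbourhood radius (default 25).
#' @param nmax maximum number of nearest neighbours used per target.
#' @param variogram optional variogram parameters `c(nugget, psill, range)`;
#'   fitted from the data when `NULL`.
#' @return numeric vector of predictions, `NA` where no observation lies
#'   within the radius.
#' @export
krige_local <- function(targets, obs_xy, obs_values, radius_km = 25,
                        nmax = 24, variogram = NULL) {
  targets <- as.matrix(targets); obs_xy <- as.matrix(obs_xy)
  stopifnot(ncol(targets) == 2, ncol(obs_xy) == 2,
            nrow(obs_xy) == length(obs_values))
  ok <- is.finite(obs_values)
  obs_xy <- obs_xy[ok, , drop = FALSE]; obs_values <- obs_values[ok]
  n <- length(obs_values)
  out <- rep(NA_real_, nrow(targets))
  if (n == 0) return(out)
  if (is.null(variogram)) variogram <- fit_variogram_exp(obs_xy, obs_values)
  vg <- function(h) variogram[1] * (h > 0) +
    variogram[2] * (1 - exp(-h / variogram[3]))
  for (i in seq_len(nrow(targets))) {
    d <- sqrt((obs_xy[, 1] - targets[i, 1])^2 + (obs_xy[, 2] - targets[i, 2])^2)
    nb <- which(d <= radius_km)
    if (!length(nb)) next
    if (length(nb) > nmax) nb <- nb[order(d[nb])[seq_len(nmax)]]
    if (length(nb) == 1) { out[i] <- obs_values[nb]; next }
    # coincident observation: exactness shortcut (also avoids a singular
    # system when duplicate coordinates are present)
    hit <- nb[d[nb] < 1e-9]
    if (length(hit)) { out[i] <- mean(obs_values[hit]); next }
    xy <- obs_xy[nb, , drop = FALSE]
    hmat <- as.matrix(stats::dist(xy))
    m <- length(nb)
    A <- rbind(cbind(vg(hmat), 1), c(rep(1, m), 0))
    b <- c(vg(d[nb]), 1)
    lambda <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(lambda) || any(!is.finite(lambda))) {
      warning("singular kriging system; falling back to inverse-distance weighting")
      w <- 1 / pmax(d[nb], 1e-9)^2
      out[i] <- sum(w * obs_values[nb]) / sum(w)
    } else {
      out[i] <- sum(lambda[seq_len(m)] * obs_values[nb])
    }
  }
  out
}

#' Fit an exponential semivariogram by weighted least squares
#'
#' Bins pairwise squared half-differences of the observations by distance
#' and fits \eqn{\gamma(h) = n + s(1 - e^{-h/a})} minimising
#' \eqn{\sum_j N_j (\hat\gamma_j - \gamma(h_j))^2 / h_j^2}.
#'
#' @param obs_xy observation coordinates (km).
#' @param obs_values observed values.
#' @param n_bins number of distance bins.
#' @param max_dist maximum pair distance used; defaults to half the maximum
#'   separation.
#' @return numeric `c(nugget, psill, range)`.
#' @export
fit_variogram_exp <- function(obs_xy, obs_values, n_bins = 12,
                              max_dist = NULL) {
  obs_xy <- as.matrix(obs_xy)
  n <- length(obs_values)
  if (n < 10) return(c(0, max(stats::var(obs_values), 1e-10), 10))
  # subsample pairs for large n
  if (n > 400) {
    idx <- sample.int(n, 400)
    obs_xy <- obs_xy[idx, , drop = FALSE]; obs_values <- obs_values[idx]
  }
  h <- as.vector(stats::dist(obs_xy))
  g <- 0.5 * as.vector(stats::dist(obs_values))^2
  if (is.null(max_dist)) max_dist <- max(h) / 2
  keep <- h > 0 & h <= max_dist
  h <- h[keep]; g <- g[keep]
  if (!length(h)) return(c(0, max(stats::var(obs_values), 1e-10), 10))
  bins <- cut(h, breaks = seq(0, max_dist, length.out = n_bins + 1))
  hb <- tapply(h, bins, mean); gb <- tapply(g, bins, mean)
  nb <- tapply(h, bins, length)
  ok <- is.finite(hb) & is.finite(gb)
  hb <- hb[ok]; gb <- gb[ok]; nb <- nb[ok]
  s0 <- max(stats::var(obs_values), 1e-10)
  obj <- function(par) {
    nug <- exp(par[1]); sill <- exp(par[2]); rng <- exp(par[3])
    fit <- nug + sill * (1 - exp(-hb / rng))
    sum(nb * (gb - fit)^2 / pmax(hb, 1)^2)
  }
  start <- log(c(0.05 * s0 + 1e-12, s0, max_dist / 3))
  opt <- tryCatch(stats::optim(start, obj), error = function(e) NULL)
  if (is.null(opt)) return(c(0.05 * s0, s0, max_dist / 3))
  unname(exp(opt$par))
}
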