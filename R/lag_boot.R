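#' Bootstrap the transfer-function calibration into per-year lag SEs
#'
#' The reconstruction error of a transfer function is shared by every
#' sample it predicts, so resampling samples within a year understates the
#' uncertainty of the annual lag. This bootstrap resamples the calibration
#' set, refits the WA-PLS model (fixed component count) on each replicate,
#' re-predicts all samples and recomputes the anchored per-year lag,
#' giving the between-replicate SE of the lag attributable to calibration.
#'
#' @param y samples x taxa abundance matrix (all samples).
#' @param x_obs observed environmental value per sample.
#' @param year sample years.
#' @param calib logical mask of calibration samples.
#' @param n_comp component count (from the full-data selection).
#' @param base_year anchor year.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param min_occ,deshrink passed to [fit_wapls()].
#' @return data frame `year`, `lag` (full-data point estimate), `se_calib`.
#' @export
lag_calibration_boot <- function(y, x_obs, year, calib, n_comp,
                                 base_year = min(year), n_boot = 100,
                                 seed = 1, min_occ = 1,
                                 deshrink = "classical") {
  ok <- is.finite(x_obs)
  y <- y[ok, , drop = FALSE]; x_obs <- x_obs[ok]; year <- year[ok]
  calib <- calib[ok]
  years <- sort(unique(year))
  stopifnot(base_year %in% years)
  lag_of <- function(rec) {
    d <- tapply(x_obs - rec, year, mean, na.rm = TRUE)
    as.numeric(d) - d[[as.character(base_year)]]
  }
  fit0 <- suppressWarnings(fit_wapls(y[calib, , drop = FALSE], x_obs[calib],
                                     a_max = n_comp, min_occ = min_occ,
                                     deshrink = deshrink))
  point <- lag_of(suppressWarnings(predict(fit0, y, n_comp = fit0$n_comp)))
  idx_cal <- which(calib)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(years))
  for (b in seq_len(n_boot)) {
    take <- sample(idx_cal, length(idx_cal), replace = TRUE)
    fb <- tryCatch(
      suppressWarnings(fit_wapls(y[take, , drop = FALSE], x_obs[take],
                                 a_max = n_comp, min_occ = min_occ,
                                 deshrink = deshrink)),
      error = function(e) NULL)
    if (is.null(fb)) next
    reps[b, ] <- lag_of(suppressWarnings(predict(fb, y,
                                                 n_comp = fb$n_comp)))
  }
  data.frame(year = years, lag = point,
             se_calib = apply(reps, 2, stats::sd, na.rm = TRUE))
}

#' Full-chain calibration bootstrap for the debt and credit headline
#'
#' Propagates transfer-function and cross-calibration uncertainty into the
#' end-of-series climatic debt and water-quality credit: each replicate
#' resamples the calibration samples, refits both WA-PLS models (fixed
#' component counts), re-predicts every sample, refits the BOD-to-degC
#' spline on the replicate's reconstructions, and recomputes the two
#' shared-intercept slope differences. This is the component of uncertainty
#' that year-resampling of the final annual series cannot see; it is
#' essential when a transfer function has little skill, in which case the
#' cross-calibration slope is an ill-conditioned ratio and the converted
#' credit is highly unstable.
#'
#' @param y samples x taxa matrix.
#' @param obs_t,obs_b observed temperature and log BOD per sample.
#' @param year sample years.
#' @param calib logical calibration mask.
#' @param a_t,a_b component counts for the two transfer functions.
#' @param base_year anchor year.
#' @param n_boot replicates (default 60).
#' @param seed integer seed.
#' @param min_occ,deshrink passed to [fit_wapls()].
#' @return list with `debt_se` and `credit_se` (SEs of the end-of-series
#'   lag estimates across replicates).
#' @export
debt_credit_calibration_boot <- function(y, obs_t, obs_b, year, calib,
                                         a_t, a_b, base_year = min(year),
                                         n_boot = 60, seed = 1,
                                         min_occ = 1,
                                         deshrink = "classical") {
  ok <- is.finite(obs_t) & is.finite(obs_b)
  y <- y[ok, , drop = FALSE]; obs_t <- obs_t[ok]; obs_b <- obs_b[ok]
  year <- year[ok]; calib <- calib[ok]
  t_final <- max(year) - base_year
  idx_cal <- which(calib)
  slope_diff <- function(obs, rec) {
    ann_o <- tapply(obs, year, mean); ann_r <- tapply(rec, year, mean)
    yrs <- as.numeric(names(ann_o)) - base_year
    d <- data.frame(value = c(ann_r, ann_o), tt = rep(yrs, 2),
                    series = factor(rep(c("rec", "obs"),
                                        each = length(yrs)),
                                    levels = c("rec", "obs")))
    stats::coef(stats::lm(value ~ tt + tt:series, d))[["tt:seriesobs"]]
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    take <- sample(idx_cal, length(idx_cal), replace = TRUE)
    out <- tryCatch({
      ft <- suppressWarnings(fit_wapls(y[take, , drop = FALSE], obs_t[take],
                                       a_max = a_t, min_occ = min_occ,
                                       deshrink = deshrink))
      fb <- suppressWarnings(fit_wapls(y[take, , drop = FALSE], obs_b[take],
                                       a_max = a_b, min_occ = min_occ,
                                       deshrink = deshrink))
      rec_t <- suppressWarnings(predict(ft, y))
      rec_b <- suppressWarnings(predict(fb, y))
      cal <- cross_calibrate(rec_t, rec_b)
      c(slope_diff(obs_t, rec_t) * t_final,
        slope_diff(cal$g(obs_b), cal$g(rec_b)) * t_final)
    }, error = function(e) c(NA_real_, NA_real_))
    out
  }, c(0, 0))
  list(debt_se = stats::sd(reps[1, ], na.rm = TRUE),
       credit_se = stats::sd(reps[2, ], na.rm = TRUE))
}
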