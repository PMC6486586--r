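#' Paired annual means of observed and reconstructed conditions
#'
#' Averages per-sample observed and reconstructed values into one national
#' pair of annual series. Samples missing either value are excluded, so the
#' two means are always computed over the same samples.
#'
#' @param d data frame with columns `year`, `observed`, `reconstructed`.
#' @return data frame: year, observed, reconstructed, n.
#' @export
annual_series <- function(d) {
  stopifnot(all(c("year", "observed", "reconstructed") %in% names(d)))
  ok <- is.finite(d$observed) & is.finite(d$reconstructed)
  d <- d[ok, ]
  if (!nrow(d)) stop("no complete observed/reconstructed pairs")
  obs <- tapply(d$observed, d$year, mean)
  rec <- tapply(d$reconstructed, d$year, mean)
  n <- tapply(d$observed, d$year, length)
  data.frame(year = as.integer(names(obs)), observed = as.numeric(obs),
             reconstructed = as.numeric(rec), n = as.integer(n),
             row.names = NULL)
}

#' Per-year environmental lag with bootstrap standard errors
#'
#' The environmental lag in year t is the mean over samples of
#' (observed - reconstructed), anchored to zero in the base year. Standard
#' errors come from a nonparametric bootstrap resampling samples within each
#' year; the anchored lag's SE combines the year's and the base year's
#' uncertainty.
#'
#' @param d data frame with `year`, `observed`, `reconstructed` per sample.
#' @param base_year anchor year (default: first year).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return data frame: year, lag, se.
#' @export
annual_lag_series <- function(d, base_year = min(d$year), n_boot = 400,
                              seed = 1) {
  ok <- is.finite(d$observed) & is.finite(d$reconstructed)
  d <- d[ok, ]
  d$diff <- d$observed - d$reconstructed
  years <- sort(unique(d$year))
  if (!base_year %in% years) stop("base year has no samples")
  mean_d <- tapply(d$diff, d$year, mean)
  set.seed(seed)
  se_d <- vapply(years, function(y) {
    v <- d$diff[d$year == y]
    if (length(v) < 2) return(NA_real_)
    stats::sd(vapply(seq_len(n_boot), function(b)
      mean(sample(v, length(v), replace = TRUE)), 0))
  }, 0)
  names(se_d) <- years
  lag <- as.numeric(mean_d) - mean_d[[as.character(base_year)]]
  se <- sqrt(se_d^2 + se_d[[as.character(base_year)]]^2)
  se[years == base_year] <- 0
  data.frame(year = years, lag = lag, se = as.numeric(se), row.names = NULL)
}

#' Cross-calibrate a water-quality stressor into temperature equivalents
#'
#' Because rising temperature and organic pollution act on stream
#' invertebrates through a shared oxygen-stress pathway, their reconstructed
#' values are strongly correlated, and a change in one can be expressed as
#' an equivalent change in the other. Fits a penalised thin-plate regression
#' spline of reconstructed temperature on reconstructed (log) BOD, with the
#' degree of smoothing chosen by generalised cross-validation, and returns
#' the fitted map as a callable function.
#'
#' @param rec_t reconstructed temperature per sample.
#' @param rec_b reconstructed (log) BOD per sample.
#' @param k spline basis dimension.
#' @return list with `g` (vectorised map BOD -> deg C), the `fit`, its
#'   effective degrees of freedom `edf` and `r_squared`.
#' @export
cross_calibrate <- function(rec_t, rec_b, k = 10) {
  ok <- is.finite(rec_t) & is.finite(rec_b)
  rec_t <- rec_t[ok]; rec_b <- rec_b[ok]
  if (length(rec_t) < 100) stop("need at least 100 paired reconstructions")
  if (stats::sd(rec_b) < 1e-8) stop("degenerate calibration: reconstructed BOD has near-zero variance")
  dat <- data.frame(rec_t = rec_t, rec_b = rec_b)
  fit <- mgcv::gam(rec_t ~ s(rec_b, bs = "tp", k = k), data = dat,
                   method = "GCV.Cp")
  list(
    g = function(b) as.numeric(stats::predict(fit, data.frame(rec_b = b))),
    fit = fit,
    edf = sum(fit$edf),
    r_squared = summary(fit)$r.sq
  )
}

#' GLS trend fit for paired observed/reconstructed annual series
#'
#' Stacks the two series and fits value ~ (year - base) with a separate
#' slope per series but one shared intercept, so the estimated lag is zero
#' in the base year. Error structures without autocorrelation (iid), with
#' first-order autoregressive (AR1) and first-order moving-average (MA1)
#' residuals are fitted by maximum likelihood -- optionally also allowing
#' different variances per series -- and the simplest model within
#' `aic_tol` AIC units of the minimum is selected. The lag in year t is
#' (slope_obs - slope_rec) * (t - base); its standard error comes from a
#' nonparametric bootstrap over years (or moving blocks of years).
#'
#' @param observed,reconstructed equal-length annual series.
#' @param years the shared year vector.
#' @param base_year intercept anchor (default: first year).
#' @param structures error structures to compare.
#' @param var_het also try per-series variance heterogeneity.
#' @param n_boot bootstrap resamples for the slope-difference SE.
#' @param seed integer seed.
#' @param boot_scheme `"case"` resamples years; `"block"` resamples moving
#'   blocks of `block_len` consecutive years.
#' @param block_len block length for the block bootstrap.
#' @param aic_tol AIC parsimony tolerance.
#' @return list with slopes, the selected structure, the AIC table, the
#'   fitted lag series, and the end-of-series lag with bootstrap SE.
#' @export
fit_paired_trend_gls <- function(observed, reconstructed, years,
                                 base_year = min(years),
                                 structures = c("iid", "ar1", "ma1"),
                                 var_het = TRUE, n_boot = 400, seed = 1,
                                 boot_scheme = c("case", "block"),
                                 block_len = 3, aic_tol = 2) {
  boot_scheme <- match.arg(boot_scheme)
  stopifnot(length(observed) == length(reconstructed),
            length(observed) == length(years))
  if (length(years) < 5) stop("need at least 5 years")
  d <- data.frame(
    value = c(reconstructed, observed),
    tt = rep(years - base_year, 2),
    series = factor(rep(c("rec", "obs"), each = length(years)),
                    levels = c("rec", "obs"))
  )
  sel <- select_gls(value ~ tt + tt:series, d, structures, var_het,
                    group = ~ series, aic_tol = aic_tol)
  co <- stats::coef(sel$fit)
  slope_rec <- co[["tt"]]
  slope_diff <- co[["tt:seriesobs"]]
  slope_obs <- slope_rec + slope_diff
  # bootstrap over years: refit the fixed-effects model on resampled years
  set.seed(seed)
  n <- length(years)
  boot_diff <- vapply(seq_len(n_boot), function(b) {
    idx <- if (boot_scheme == "case") sample.int(n, n, replace = TRUE)
    else {
      starts <- sample.int(n - block_len + 1, ceiling(n / block_len),
                           replace = TRUE)
      idx <- unlist(lapply(starts, function(s) s:(s + block_len - 1)))
      idx[seq_len(n)]
    }
    db <- data.frame(
      value = c(reconstructed[idx], observed[idx]),
      tt = rep(years[idx] - base_year, 2),
      series = factor(rep(c("rec", "obs"), each = n), levels = c("rec", "obs"))
    )
    cb <- stats::coef(stats::lm(value ~ tt + tt:series, data = db))
    cb[["tt:seriesobs"]]
  }, 0)
  se_diff <- stats::sd(boot_diff)
  lag_fitted <- slope_diff * (years - base_year)
  t_final <- max(years) - base_year
  list(
    slope_obs = slope_obs, slope_rec = slope_rec, slope_diff = slope_diff,
    intercept = co[["(Intercept)"]],
    structure = sel$structure, aic_table = sel$table, fit = sel$fit,
    slope_diff_se = se_diff,
    lag_fitted = data.frame(year = years, lag = lag_fitted),
    lag_final = slope_diff * t_final,
    lag_final_se = se_diff * t_final,
    boot_diff = boot_diff
  )
}

#' Zero-intercept GLS trend for the net environmental lag
#'
#' The net lag is zero in the base year by construction, so its trend is
#' fitted through the origin on (year - base). Error structure selection
#' follows the same within-2-AIC parsimony rule.
#'
#' @param net annual net-lag series (anchored at 0 in the base year).
#' @param years year vector.
#' @param base_year anchor year.
#' @param structures,aic_tol as in [fit_paired_trend_gls()].
#' @param n_boot,seed bootstrap control for the slope SE.
#' @return list with slope, model SE and p-value, bootstrap SE, structure
#'   and AIC table.
#' @export
net_lag_trend <- function(net, years, base_year = min(years),
                          structures = c("iid", "ar1", "ma1"),
                          n_boot = 400, seed = 1, aic_tol = 2) {
  stopifnot(length(net) == length(years))
  d <- data.frame(value = net, tt = years - base_year)
  sel <- select_gls(value ~ 0 + tt, d, structures, var_het = FALSE,
                    group = NULL, aic_tol = aic_tol)
  tt_row <- if (inherits(sel$fit, "lm")) {
    co <- summary(sel$fit)$coefficients["tt", ]
    c(Value = unname(co[1]), Std.Error = unname(co[2]),
      `p-value` = unname(co[4]))
  } else summary(sel$fit)$tTable["tt", ]
  set.seed(seed)
  n <- length(years)
  boot_slope <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    sum(net[idx] * (years[idx] - base_year)) /
      sum((years[idx] - base_year)^2)
  }, 0)
  list(slope = unname(tt_row["Value"]), se = unname(tt_row["Std.Error"]),
       p_value = unname(tt_row["p-value"]), boot_se = stats::sd(boot_slope),
       structure = sel$structure, aic_table = sel$table, fit = sel$fit,
       lag_final = unname(tt_row["Value"]) * (max(years) - base_year))
}

# Fit a mean model under candidate error structures and apply the
# simplest-within-aic_tol rule. Structures are ordered simple -> complex.
select_gls <- function(formula, data, structures, var_het, group,
                       aic_tol = 2) {
  cand <- list()
  time_form <- if (is.null(group)) ~ tt else stats::as.formula("~ tt | series")
  for (s in structures) {
    corr <- switch(s, iid = NULL,
                   ar1 = nlme::corAR1(form = time_form),
                   ma1 = nlme::corARMA(q = 1, form = time_form))
    vlist <- list(none = NULL)
    if (var_het && !is.null(group))
      vlist$het <- nlme::varIdent(form = stats::as.formula("~ 1 | series"))
    for (vn in names(vlist)) {
      nm <- if (vn == "none") s else paste0(s, "+varhet")
      fit <- tryCatch(
        nlme::gls(formula, data = data, correlation = corr,
                  weights = vlist[[vn]], method = "ML"),
        error = function(e) NULL)
      if (!is.null(fit)) cand[[nm]] <- fit
    }
  }
  if (!length(cand)) {
    # degenerate data (e.g. an exact linear fit) can defeat the GLS
    # likelihood machinery; ordinary least squares is then exact
    cand[["ols"]] <- stats::lm(formula, data = data)
  }
  npar <- vapply(cand, function(m) length(stats::coef(m)) +
                   length(unlist(m$modelStruct)) + 1, 0)
  if ("ols" %in% names(cand)) npar[] <- 1
  aic <- vapply(cand, stats::AIC, 0)
  delta <- if (any(is.finite(aic))) aic - min(aic) else rep(0, length(aic))
  delta[is.nan(delta)] <- 0          # ties among -Inf AICs (exact fits)
  tab <- data.frame(structure = names(cand), npar = npar, aic = aic,
                    delta_aic = delta, row.names = NULL)
  ok <- tab$delta_aic <= aic_tol
  pick <- tab$structure[ok][which.min(tab$npar[ok])]
  list(fit = cand[[pick]], structure = pick, table = tab)
}

#' Assemble climatic debt, water-quality credit and the net lag
#'
#' Converts paired observed/reconstructed annual series for temperature and
#' (log) BOD into the three accounting quantities, all in degrees Celsius:
#' the climatic debt (temperature lag, positive when observed warming
#' outruns the community-implied warming), the water-quality credit (the
#' BOD lag after mapping BOD through the cross-calibration `g`; negative
#' when observed quality improves faster than the community implies), and
#' the net environmental lag (their sum). All per-year series are anchored
#' at zero in the base year; trend-based estimates come from shared-
#' intercept GLS fits with bootstrap SEs.
#'
#' @param temp_annual data frame year/observed/reconstructed for water
#'   temperature (deg C).
#' @param bod_annual same for BOD on the log scale.
#' @param g cross-calibration map from [cross_calibrate()] (its `g`).
#' @param base_year anchor year.
#' @param n_boot,seed,structures,var_het passed to the GLS fits.
#' @return list with the per-year `series` (year, debt, credit, net), the
#'   three trend fits (`temp_fit`, `wq_fit`, `net_fit`), a log-scale BOD
#'   fit (`bod_log_fit`) and headline end-of-series estimates.
#' @export
compute_debt_credit <- function(temp_annual, bod_annual, g,
                                base_year = min(temp_annual$year),
                                n_boot = 400, seed = 1,
                                structures = c("iid", "ar1", "ma1"),
                                var_het = TRUE) {
  stopifnot(identical(temp_annual$year, bod_annual$year))
  years <- temp_annual$year
  obs_b_c <- g(bod_annual$observed)
  rec_b_c <- g(bod_annual$reconstructed)
  anchor <- function(v) v - v[years == base_year]
  debt <- anchor(temp_annual$observed - temp_annual$reconstructed)
  credit <- anchor(obs_b_c - rec_b_c)
  series <- data.frame(year = years, debt = debt, credit = credit,
                       net = debt + credit)
  temp_fit <- fit_paired_trend_gls(temp_annual$observed,
                                   temp_annual$reconstructed, years,
                                   base_year, structures, var_het,
                                   n_boot, seed)
  wq_fit <- fit_paired_trend_gls(obs_b_c, rec_b_c, years, base_year,
                                 structures, var_het, n_boot, seed + 1)
  bod_log_fit <- fit_paired_trend_gls(bod_annual$observed,
                                      bod_annual$reconstructed, years,
                                      base_year, structures, var_het,
                                      n_boot, seed + 2)
  net_fit <- net_lag_trend(series$net, years, base_year, structures,
                           n_boot, seed + 3)
  list(series = series,
       temp_fit = temp_fit, wq_fit = wq_fit, bod_log_fit = bod_log_fit,
       net_fit = net_fit,
       debt_final = temp_fit$lag_final, debt_final_se = temp_fit$lag_final_se,
       credit_final = wq_fit$lag_final, credit_final_se = wq_fit$lag_final_se,
       net_final = temp_fit$lag_final + wq_fit$lag_final)
}
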