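#' Annual median of monthly determinand values, censoring-aware
#'
#' Summarises the monthly samples from one site and one annual window
#' (the 12 months March-February preceding spring biological sampling) into
#' a single annual median. Site-years with fewer than `min_months` monthly
#' samples are rejected rather than summarised. When more than half of the
#' values lie below the detection limit, the median is imputed by regression
#' on order statistics ([ros_impute()]); otherwise the median of the
#' uncensored values is returned.
#'
#' @param values numeric vector of monthly values; censored observations are
#'   reported at their detection limit.
#' @param censored logical vector, `TRUE` where the value is a below-detection
#'   substitution.
#' @param min_months minimum number of monthly samples required (default 9).
#' @return a list with `value` (the annual median, `NA` if rejected),
#'   `status` (`"ok"` or `"rejected"`), and `provenance`
#'   (`"measured"`, `"ros"`, or `NA` if rejected).
#' @export
annual_median <- function(values, censored = rep(FALSE, length(values)),
                          min_months = 9) {
  stopifnot(length(values) == length(censored))
  keep <- is.finite(values)
  values <- values[keep]; censored <- as.logical(censored[keep])
  if (length(values) < min_months) {
    return(list(value = NA_real_, status = "rejected", provenance = NA_character_))
  }
  frac_cens <- mean(censored)
  if (frac_cens > 0.5) {
    if (all(censored)) {
      return(list(value = NA_real_, status = "rejected", provenance = NA_character_))
    }
    med <- ros_impute(values, censored)$median
    return(list(value = med, status = "ok", provenance = "ros"))
  }
  list(value = stats::median(values[!censored]), status = "ok",
       provenance = "measured")
}

#' Regression on order statistics for left-censored data
#'
#' Helsel-style robust ROS for water-chemistry values with below-detection
#' censoring. Plotting positions are computed with the Hirsch-Stedinger
#' method (which accommodates multiple detection limits), the log of the
#' uncensored values is regressed on the corresponding standard-normal
#' quantiles, censored observations are imputed from the fitted line at
#' their own plotting positions, and summary statistics are taken over the
#' combined set of observed and imputed values.
#'
#' @param values numeric vector; censored observations at their detection
#'   limit.
#' @param censored logical vector flagging below-detection values.
#' @return list with `median` and `mean` of the combined set, the `imputed`
#'   values for the censored observations, and the regression `coef`.
#' @references Helsel, D.R. (2005) Nondetects and Data Analysis.
#' @export
ros_impute <- function(values, censored) {
  stopifnot(length(values) == length(censored))
  censored <- as.logical(censored)
  if (all(censored)) stop("fully censored: no uncensored values to fit")
  if (any(values <= 0)) stop("ROS requires strictly positive values")
  if (!any(censored)) {
    return(list(median = stats::median(values), mean = mean(values),
                imputed = numeric(0), coef = c(NA_real_, NA_real_)))
  }
  pp <- hirsch_stedinger_pp(values, censored)
  obs <- values[!censored]
  q_obs <- stats::qnorm(pp$p_uncensored)
  fit <- stats::lm.fit(cbind(1, q_obs), log(obs))
  beta <- fit$coefficients
  imputed <- exp(beta[1] + beta[2] * stats::qnorm(pp$p_censored))
  combined <- c(obs, imputed)
  list(median = stats::median(combined), mean = mean(combined),
       imputed = unname(imputed), coef = unname(beta))
}

# Hirsch-Stedinger plotting positions for left-censored data.
# Returns non-exceedance probabilities for the uncensored values (in the
# order of values[!censored]) and for the censored values.
hirsch_stedinger_pp <- function(values, censored) {
  limits <- sort(unique(values[censored]))
  # interval j holds uncensored values in [limits[j], limits[j+1])
  bounds <- c(limits, Inf)
  m <- length(limits)
  # pe[j]: probability of exceeding limits[j]; recursion from the largest
  # limit downwards (Hirsch & Stedinger 1987)
  pe <- numeric(m + 1)  # pe[m+1] = 0 (exceeding "Inf")
  for (j in m:1) {
    A <- sum(!censored & values >= bounds[j] & values < bounds[j + 1])
    B <- sum(values < bounds[j]) + sum(censored & values == bounds[j])
    pe_j1 <- if (j == m) 0 else pe[j + 1]
    pe[j] <- if (A + B == 0) pe_j1 else pe_j1 + A / (A + B) * (1 - pe_j1)
  }
  # uncensored values below the smallest limit form interval 0 with pe0 = 1
  pe_full <- c(1, pe[seq_len(m)])
  lower_full <- c(-Inf, limits)
  upper_full <- c(limits, Inf)
  pe_next <- c(pe[seq_len(m)], 0)
  p_unc <- numeric(sum(!censored))
  unc_vals <- values[!censored]
  for (j in seq_len(m + 1)) {
    in_j <- which(unc_vals >= lower_full[j] & unc_vals < upper_full[j])
    if (!length(in_j)) next
    r <- rank(unc_vals[in_j], ties.method = "first")
    Aj <- length(in_j)
    p_unc[in_j] <- (1 - pe_full[j]) + (pe_full[j] - pe_next[j]) * r / (Aj + 1)
  }
  p_cen <- numeric(sum(censored))
  cen_vals <- values[censored]
  for (j in seq_len(m)) {
    at_j <- which(cen_vals == limits[j])
    if (!length(at_j)) next
    Cj <- length(at_j)
    p_cen[at_j] <- (1 - pe[j]) * seq_len(Cj) / (Cj + 1)
  }
  list(p_uncensored = p_unc, p_censored = p_cen)
}

#' Impute nitrate from total oxidised nitrogen (TON)
#'
#' Monitoring programmes sometimes record TON in place of nitrate. Because
#' nitrate makes up nearly all of TON in rivers, missing nitrate values can
#' be filled by a simple linear calibration of nitrate on TON fitted where
#' both determinands were measured.
#'
#' @param ton TON values for which nitrate is to be imputed.
#' @param calib_nitrate,calib_ton paired calibration measurements.
#' @return list with `nitrate` (imputed values), `slope`, `intercept` and
#'   calibration `r_squared`.
#' @export
impute_nitrate <- function(ton, calib_nitrate, calib_ton) {
  ok <- is.finite(calib_nitrate) & is.finite(calib_ton)
  if (sum(ok) < 10) stop("fewer than 10 calibration pairs")
  fit <- stats::lm(calib_nitrate[ok] ~ calib_ton[ok])
  co <- unname(stats::coef(fit))
  list(nitrate = co[1] + co[2] * ton,
       slope = co[2], intercept = co[1],
       r_squared = summary(fit)$r.squared)
}

#' Standardise discharge to catchment runoff
#'
#' Divides discharge by catchment area to give a runoff depth that is
#' comparable across streams of different size.
#'
#' @param q discharge in cubic metres per second.
#' @param area_km2 catchment area in square kilometres.
#' @return runoff in millimetres per day.
#' @examples
#' standardize_discharge(1, 86.4)  # 1 mm/day
#' @export
standardize_discharge <- function(q, area_km2) {
  if (any(area_km2 <= 0)) stop("catchment area must be positive")
  if (any(q < 0)) stop("discharge must be non-negative")
  q * 86400 / (area_km2 * 1e6) * 1000
}
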