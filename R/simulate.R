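#' Scenario configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the synthetic national monitoring
#' scenario: the site network, the linear warming and BOD trends, the
#' first-order community tracking rate (the lag-generating mechanism), the
#' Gaussian taxon niches along the latent oxygen-stress axis, and the
#' observation process (annual sampling probability, Poisson counts
#' coarsened to log10 abundance classes, monthly chemistry with seasonal
#' noise and detection-limit censoring).
#'
#' The latent stress axis is a linear combination of water temperature and
#' log BOD (`stress_weights`), reflecting their shared action on oxygen
#' availability. Communities follow the tracked environment
#' E*(t) = (1-r) E*(t-1) + r E(t); with tracking rate r = 1 they are always
#' at equilibrium, and under a linear trend of slope b the lag converges to
#' b(1-r)/r.
#'
#' @param n_sites number of biological sampling sites.
#' @param years inclusive vector of sampling years.
#' @param n_taxa number of taxa (family-level analogues).
#' @param warming_slope linear water-temperature trend b, deg C per year.
#' @param bod_slope linear trend c of log BOD per year (negative =
#'   improving water quality).
#' @param tracking_rate first-order community tracking rate r in (0, 1].
#' @param stress_weights named numeric `c(temperature=, bod=)`: loadings of
#'   temperature (per deg C) and log BOD (per log unit) on the stress axis.
#' @param sampling_prob probability a site is sampled in a given year.
#' @param detection_limit detection limit applied to orthophosphate, mg/l.
#' @param env_noise_sd named numeric `c(temperature=, bod=)`: sd of annual
#'   site-level noise (deg C; log units).
#' @param month_dropout probability a monthly chemistry sample is missing.
#' @param obs_model `"poisson"` for Poisson counts, `"expected"` for
#'   noise-free expected abundances.
#' @param abundance_format `"midpoint"` (log10-class midpoints, the recorded
#'   format) or `"raw"`.
#' @param domain_km side of the square study region, km.
#' @param taxa optional data frame (`optimum`, `tolerance`, `height`)
#'   overriding the generated niches.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 300, years = 1991:2011, n_taxa = 78,
                            warming_slope = 0.05, bod_slope = -0.02,
                            tracking_rate = 0.25,
                            stress_weights = c(temperature = 1, bod = 2),
                            sampling_prob = 0.8, detection_limit = 0.05,
                            env_noise_sd = c(temperature = 0.2, bod = 0.05),
                            month_dropout = 0.05,
                            obs_model = c("poisson", "expected"),
                            abundance_format = c("midpoint", "raw"),
                            domain_km = 200, taxa = NULL, seed = 1) {
  obs_model <- match.arg(obs_model)
  abundance_format <- match.arg(abundance_format)
  cfg <- list(n_sites = as.integer(n_sites), years = as.integer(years),
              n_taxa = as.integer(n_taxa), warming_slope = warming_slope,
              bod_slope = bod_slope, tracking_rate = tracking_rate,
              stress_weights = stress_weights,
              sampling_prob = sampling_prob,
              detection_limit = detection_limit,
              env_noise_sd = env_noise_sd, month_dropout = month_dropout,
              obs_model = obs_model, abundance_format = abundance_format,
              domain_km = domain_km, taxa = taxa, seed = as.integer(seed))
  num <- unlist(cfg[c("warming_slope", "bod_slope", "tracking_rate",
                      "stress_weights", "sampling_prob", "detection_limit",
                      "env_noise_sd", "month_dropout", "domain_km")])
  if (any(!is.finite(num))) stop("non-finite configuration value")
  if (cfg$tracking_rate <= 0 || cfg$tracking_rate > 1)
    stop("tracking_rate must be in (0, 1]")
  if (cfg$sampling_prob <= 0 || cfg$sampling_prob > 1)
    stop("sampling_prob must be in (0, 1]")
  if (length(cfg$years) < 2) stop("need at least two years")
  if (!all(c("temperature", "bod") %in% names(cfg$stress_weights)))
    stop("stress_weights must name 'temperature' and 'bod'")
  if (!is.null(taxa)) {
    stopifnot(all(c("optimum", "tolerance", "height") %in% names(taxa)))
    if (any(taxa$tolerance <= 0)) stop("taxon tolerances must be positive")
    if (any(taxa$height <= 0)) stop("taxon heights must be positive")
    cfg$n_taxa <- nrow(taxa)
  }
  structure(cfg, class = "scenario_config")
}

#' Named scenario presets
#'
#' `"default"`: both stressors load on the stress axis, warming plus BOD
#' improvement. `"warming_only"`: the temperature pathway in isolation
#' (BOD neither trends nor influences the community) -- the scenario in
#' which the closed-form temperature lag b(1-r)(1-(1-r)^t)/r is exactly the
#' generator truth. `"bod_only"`: the mirror image for water quality.
#' `"null_tracking"`: warming with instantaneous tracking (r = 1), so every
#' lag is zero in truth.
#'
#' @param name preset name.
#' @param ... overrides passed on to [scenario_config()].
#' @return a `scenario_config`.
#' @export
scenario_preset <- function(name = c("default", "warming_only", "bod_only",
                                     "null_tracking"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    default = list(),
    warming_only = list(bod_slope = 0,
                        stress_weights = c(temperature = 1, bod = 0)),
    bod_only = list(warming_slope = 0, bod_slope = -0.04,
                    stress_weights = c(temperature = 0, bod = 2)),
    null_tracking = list(bod_slope = 0, tracking_rate = 1,
                         stress_weights = c(temperature = 1, bod = 0))
  )
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

#' Simulate the site network and annual environment
#'
#' Places sites uniformly in the study region, derives spatially smooth
#' baselines for water temperature and log BOD (so spatial interpolation
#' has structure to exploit), and generates per site-year observed values
#' as baseline + linear trend + annual noise. Site attributes (altitude,
#' channel slope, distance from source, urban land fraction) are generated
#' coherently with the environmental fields: cooler rivers sit at higher
#' altitude, more polluted rivers drain more urban catchments.
#'
#' @param config a `scenario_config`.
#' @return list with `sites` (attributes) and `env` (site-year table with
#'   observed and noise-free true values; `t` is years since the first
#'   year).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  D <- config$domain_km
  n <- config$n_sites
  x <- stats::runif(n, 0, D); y <- stats::runif(n, 0, D)
  t0_smooth <- 11 + 2 * sin(2 * pi * x / D) + 2 * cos(2 * pi * y / D)
  t0 <- t0_smooth + stats::rnorm(n, 0, 0.5)
  b0_smooth <- log(1.8) + 0.45 * cos(2 * pi * x / D) + 0.45 * sin(2 * pi * y / D)
  b0 <- b0_smooth + stats::rnorm(n, 0, 0.15)
  n0 <- log(2.0) + 0.5 * sin(2 * pi * y / D) + stats::rnorm(n, 0, 0.2)
  p0 <- log(0.08) + 0.4 * cos(2 * pi * y / D) + stats::rnorm(n, 0, 0.2)
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)), x = x, y = y,
    altitude = pmax(5, 500 - 45 * (t0 - 8) + stats::rnorm(n, 0, 30)),
    slope = exp(stats::rnorm(n, log(4), 0.6)),
    distance = stats::runif(n, 2, 80),
    urban = pmin(0.95, pmax(0, stats::plogis(2 * (b0 - log(1.8)) +
                                               stats::rnorm(n, 0, 0.5)) * 0.6)),
    t0 = t0, logb0 = b0, logn0 = n0, logp0 = p0
  )
  tt <- config$years - config$years[1]
  env <- expand.grid(site_id = sites$site_id, year = config$years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  env <- env[order(env$site_id, env$year), ]
  rownames(env) <- NULL
  idx <- match(env$site_id, sites$site_id)
  env$t <- env$year - config$years[1]
  env$true_temperature <- sites$t0[idx] + config$warming_slope * env$t
  env$true_log_bod <- sites$logb0[idx] + config$bod_slope * env$t
  env$temperature <- env$true_temperature +
    stats::rnorm(nrow(env), 0, config$env_noise_sd[["temperature"]])
  env$log_bod <- env$true_log_bod +
    stats::rnorm(nrow(env), 0, config$env_noise_sd[["bod"]])
  env$bod <- exp(env$log_bod)
  env$true_log_nitrate <- sites$logn0[idx] - 0.01 * env$t
  env$true_log_phosphate <- sites$logp0[idx] - 0.03 * env$t
  list(sites = sites, env = env)
}

#' First-order tracking of an environmental series
#'
#' The community-tracked environment follows
#' E*(t) = (1 - r) E*(t-1) + r E(t) with E*(t0) = E(t0). Under a linear
#' trend of slope b the lag E - E* converges to b(1-r)/r; with r = 1 the
#' tracked series equals the input exactly.
#'
#' @param x numeric series in time order.
#' @param r tracking rate in (0, 1].
#' @return tracked series of the same length.
#' @export
track_series <- function(x, r) {
  if (r <= 0 || r > 1) stop("tracking rate must be in (0, 1]")
  out <- x
  for (t in seq_along(x)[-1]) out[t] <- (1 - r) * out[t - 1] + r * x[t]
  out
}

#' Apply first-order tracking to a site-year environment table
#'
#' Adds `tracked_temperature` and `tracked_log_bod` columns by applying
#' [track_series()] within each site (in year order) to the observed
#' series.
#'
#' @param env environment table from [simulate_environment()].
#' @param r tracking rate in (0, 1].
#' @return `env` with tracked columns added.
#' @export
track_environment <- function(env, r) {
  if (r <= 0 || r > 1) stop("tracking rate must be in (0, 1]")
  env <- env[order(env$site_id, env$year), ]
  env$tracked_temperature <-
    stats::ave(env$temperature, env$site_id, FUN = function(v) track_series(v, r))
  env$tracked_log_bod <-
    stats::ave(env$log_bod, env$site_id, FUN = function(v) track_series(v, r))
  env
}

#' Closed-form expected temperature lag of the generator
#'
#' Under a linear trend of slope b and tracking rate r, the lag
#' E(t) - E*(t) after t steps is b (1-r) (1 - (1-r)^t) / r, converging to
#' b (1-r) / r.
#'
#' @param config a `scenario_config`.
#' @param t years elapsed since the first year (vectorised).
#' @return expected lag in deg C.
#' @export
expected_lag <- function(config, t) {
  b <- config$warming_slope; r <- config$tracking_rate
  b * (1 - r) * (1 - (1 - r)^t) / r
}

#' Generate Gaussian taxon niches along the stress axis
#'
#' Optima are spread evenly (with jitter) across the stress range realised
#' by the scenario, tolerances are uniform on 1-2 stress units and heights
#' log-normal, so the community turns over smoothly along the gradient.
#'
#' @param config a `scenario_config`.
#' @param stress_range numeric range the optima should cover.
#' @return data frame `taxon`, `optimum`, `tolerance`, `height`.
#' @export
generate_taxa <- function(config, stress_range) {
  if (!is.null(config$taxa)) {
    tx <- config$taxa
    tx$taxon <- if (is.null(tx$taxon)) sprintf("T%02d", seq_len(nrow(tx))) else tx$taxon
    return(tx)
  }
  k <- config$n_taxa
  span <- diff(stress_range)
  mu <- seq(stress_range[1] - 0.05 * span, stress_range[2] + 0.05 * span,
            length.out = k) + stats::rnorm(k, 0, 0.02 * span)
  data.frame(taxon = sprintf("T%02d", seq_len(k)), optimum = mu,
             tolerance = stats::runif(k, 1, 2),
             height = exp(stats::rnorm(k, log(30), 0.4)))
}

#' Simulate community samples from the tracked environment
#'
#' The latent oxygen stress at a site-year is the weighted combination of
#' tracked temperature and tracked log BOD; each taxon's expected abundance
#' is a Gaussian response h exp(-(stress - mu)^2 / (2 sigma^2)); counts are
#' Poisson draws (or the expected values for noise-free runs) and are
#' recorded as log10 abundance-class midpoints, matching the format of the
#' national monitoring data. Each site is sampled in a given year with
#' probability `sampling_prob`, independently across years, which yields
#' the irregular site-by-year coverage (with consecutive-year pairs) that
#' the transition tally needs.
#'
#' @param env tracked environment table from [track_environment()].
#' @param config a `scenario_config`.
#' @param taxa optional niche table (generated when `NULL`).
#' @return list with `samples` (sample_id, site_id, year, stress), `y`
#'   (samples x taxa abundance matrix in the requested format), `counts`
#'   (raw counts) and `taxa`.
#' @export
simulate_community <- function(env, config, taxa = NULL) {
  stopifnot(all(c("tracked_temperature", "tracked_log_bod") %in% names(env)))
  w <- config$stress_weights
  stress <- w[["temperature"]] * env$tracked_temperature +
    w[["bod"]] * env$tracked_log_bod
  if (is.null(taxa)) taxa <- generate_taxa(config, range(stress))
  sampled <- stats::runif(nrow(env)) <= config$sampling_prob
  env_s <- env[sampled, ]; stress_s <- stress[sampled]
  lambda <- outer(stress_s, taxa$optimum, function(s, m) -(s - m)^2) /
    rep(2 * taxa$tolerance^2, each = length(stress_s))
  lambda <- exp(lambda) * rep(taxa$height, each = length(stress_s))
  counts <- if (config$obs_model == "poisson")
    matrix(stats::rpois(length(lambda), lambda), nrow(lambda)) else lambda
  y <- if (config$abundance_format == "midpoint")
    matrix(to_log10_class_midpoint(counts), nrow(counts)) else counts
  colnames(y) <- colnames(counts) <- taxa$taxon
  list(
    samples = data.frame(sample_id = sprintf("K%05d", seq_len(nrow(env_s))),
                         site_id = env_s$site_id, year = env_s$year,
                         stress = stress_s, row.names = NULL),
    y = y, counts = counts, taxa = taxa
  )
}

#' Simulate monthly chemistry and temperature records
#'
#' Expands the annual true values into 12 monthly samples per site-year at
#' dedicated water-chemistry monitoring points (offset a short distance
#' from the biological sites, as in national monitoring networks):
#' temperature gets an additive seasonal cycle, chemistry a multiplicative
#' (log-scale) one, both with noise. Orthophosphate values below the
#' detection limit are flagged censored and reported at the limit. Months
#' are dropped at random with probability `month_dropout`, exercising the
#' at-least-nine-months rule downstream. For a fraction of site-years
#' nitrate is recorded as total oxidised nitrogen (TON) instead, with
#' paired measurements at other site-years available for calibration.
#'
#' @param env environment table (annual true values).
#' @param sites site table from [simulate_environment()].
#' @param config a `scenario_config`.
#' @return list with `chem_sites` (monitoring-point coordinates) and
#'   `monthly` (site_id, window_year, month, determinand, value, censored).
#' @export
simulate_monthly_chemistry <- function(env, sites, config) {
  n <- nrow(sites)
  chem_sites <- data.frame(
    site_id = sprintf("W%03d", seq_len(n)),
    bio_site = sites$site_id,
    x = sites$x + stats::rnorm(n, 0, 2),
    y = sites$y + stats::rnorm(n, 0, 2)
  )
  idx <- match(env$site_id, sites$site_id)
  m <- 1:12
  seas_t <- 5 * cos(2 * pi * (m - 7.5) / 12)     # zero-median over 12 months
  seas_c <- 0.15 * cos(2 * pi * (m - 1.5) / 12)
  rows <- vector("list", 4)
  mk <- function(det, annual, seasonal, sd_m, log_scale) {
    nn <- length(annual) * 12
    base <- rep(annual, each = 12)
    seas <- rep(seasonal, times = length(annual))
    val <- if (log_scale) exp(base + seas + stats::rnorm(nn, 0, sd_m))
    else base + seas + stats::rnorm(nn, 0, sd_m)
    data.frame(site_id = rep(chem_sites$site_id[idx], each = 12),
               window_year = rep(env$year, each = 12),
               month = rep(m, times = length(annual)),
               determinand = det, value = val, censored = FALSE)
  }
  rows[[1]] <- mk("temperature", env$true_temperature, seas_t, 0.8, FALSE)
  rows[[2]] <- mk("bod", env$true_log_bod, seas_c, 0.15, TRUE)
  rows[[3]] <- mk("nitrate", env$true_log_nitrate, seas_c, 0.15, TRUE)
  rows[[4]] <- mk("orthophosphate", env$true_log_phosphate, seas_c, 0.2, TRUE)
  monthly <- do.call(rbind, rows)
  # orthophosphate censoring at the detection limit
  cen <- monthly$determinand == "orthophosphate" &
    monthly$value < config$detection_limit
  monthly$censored[cen] <- TRUE
  monthly$value[cen] <- config$detection_limit
  # record nitrate as TON for some site-years; keep paired nitrate+TON at
  # others so the calibration regression has data
  sy <- unique(monthly[monthly$determinand == "nitrate",
                       c("site_id", "window_year")])
  grp <- sample(c("nitrate", "ton_only", "both"), nrow(sy), replace = TRUE,
                prob = c(0.5, 0.2, 0.3))
  key_all <- paste(monthly$site_id, monthly$window_year)
  key_sy <- paste(sy$site_id, sy$window_year)
  is_nit <- monthly$determinand == "nitrate"
  ton_from <- function(v) v / 0.99 * exp(stats::rnorm(length(v), 0, 0.01))
  both_rows <- monthly[is_nit & key_all %in% key_sy[grp == "both"], ]
  if (nrow(both_rows)) {
    both_rows$determinand <- "ton"
    both_rows$value <- ton_from(both_rows$value)
    monthly <- rbind(monthly, both_rows)
  }
  only_idx <- is_nit & key_all %in% key_sy[grp == "ton_only"]
  monthly$determinand[only_idx] <- "ton"
  monthly$value[only_idx] <- ton_from(monthly$value[only_idx])
  # month dropout
  if (config$month_dropout > 0)
    monthly <- monthly[stats::runif(nrow(monthly)) > config$month_dropout, ]
  rownames(monthly) <- NULL
  list(chem_sites = chem_sites, monthly = monthly)
}

#' Simulate annual discharge records at gauging stations
#'
#' A subset of monitoring points carries a flow gauge with a known
#' catchment area; annual median discharge scales with catchment area at
#' roughly 1 mm/day of runoff with lognormal year-to-year variability.
#'
#' @param chem_sites monitoring points from [simulate_monthly_chemistry()].
#' @param config a `scenario_config`.
#' @return data frame site_id, year, discharge (m3/s), catchment_km2.
#' @export
simulate_discharge <- function(chem_sites, config) {
  gauges <- chem_sites[seq_len(nrow(chem_sites)) %% 2 == 1, ]
  area <- exp(stats::rnorm(nrow(gauges), log(100), 0.8))
  d <- expand.grid(i = seq_len(nrow(gauges)), year = config$years,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(site_id = gauges$site_id[d$i], year = d$year,
             discharge = area[d$i] / 86.4 *
               exp(stats::rnorm(nrow(d), 0, 0.3)),
             catchment_km2 = area[d$i])
}

#' Simulate class-label sequences from annual transition matrices
#'
#' Direct generator for the Markov layer: initial states are drawn from the
#' stationary distribution of the first matrix, sites then step through the
#' given per-year matrices, and site-years are observed with probability
#' `sampling_prob` (introducing missing years as in real monitoring).
#'
#' @param P_list list of row-stochastic K x K matrices, one per annual
#'   transition; all the same dimension.
#' @param n_sites number of sites.
#' @param years optional year labels (length `length(P_list) + 1`).
#' @param sampling_prob per site-year observation probability.
#' @param seed integer seed.
#' @return data frame `site_id`, `year`, `class` of the observed labels.
#' @export
simulate_markov_sequences <- function(P_list, n_sites, years = NULL,
                                      sampling_prob = 1, seed = 1) {
  lapply(P_list, check_stochastic)
  k <- nrow(P_list[[1]])
  if (any(vapply(P_list, nrow, 0L) != k)) stop("matrices must share a dimension")
  if (is.null(years)) years <- seq_len(length(P_list) + 1)
  stopifnot(length(years) == length(P_list) + 1)
  set.seed(seed)
  states <- matrix(NA_integer_, n_sites, length(years))
  w0 <- stationary_distribution(P_list[[1]])
  states[, 1] <- sample.int(k, n_sites, replace = TRUE, prob = w0)
  for (t in seq_along(P_list)) {
    for (s in seq_len(k)) {
      idx <- which(states[, t] == s)
      if (length(idx))
        states[idx, t + 1] <- sample.int(k, length(idx), replace = TRUE,
                                         prob = P_list[[t]][s, ])
    }
  }
  d <- data.frame(site_id = rep(sprintf("S%04d", seq_len(n_sites)),
                                times = length(years)),
                  year = rep(years, each = n_sites),
                  class = as.vector(states))
  d[stats::runif(nrow(d)) <= sampling_prob, ]
}

#' Generate a complete synthetic scenario
#'
#' Runs the whole generator: environment, tracked environment, community
#' samples, monthly chemistry, discharge, and the ground truth needed by
#' validation (the closed-form expected temperature lag per year). All
#' randomness flows from `config$seed`; identical configurations give
#' bit-identical datasets.
#'
#' @param config a `scenario_config`.
#' @return list with `config`, `sites`, `env`, `community`, `chem_sites`,
#'   `monthly`, `discharge` and `truth`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  base <- simulate_environment(config)            # seeds the RNG
  env <- track_environment(base$env, config$tracking_rate)
  community <- simulate_community(env, config)
  chem <- simulate_monthly_chemistry(env, base$sites, config)
  discharge <- simulate_discharge(chem$chem_sites, config)
  tt <- config$years - config$years[1]
  truth <- list(
    expected_temperature_lag = data.frame(year = config$years,
                                          lag = expected_lag(config, tt)),
    asymptotic_lag = config$warming_slope *
      (1 - config$tracking_rate) / config$tracking_rate
  )
  list(config = config, sites = base$sites, env = env,
       community = community, chem_sites = chem$chem_sites,
       monthly = chem$monthly, discharge = discharge, truth = truth)
}
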