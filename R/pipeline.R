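#' Run the full credit-debt analysis pipeline
#'
#' Orchestrates the five analysis stages over either a synthetic scenario
#' or a dataset on disk: preprocess (annual censoring-aware chemistry
#' medians kriged to the biology locations), classify (dissimilarity,
#' clustering into K ordered classes, annual prevalence), markov (transition
#' tally, loglinear model selection, per-year matrices and stability
#' diagnostics), transfer (WA-PLS calibration on the baseline window with
#' leave-one-out component selection, reconstruction of temperature and log
#' BOD for every sample, nutrient-discharge PCA composite) and debt_credit
#' (annual lags, BOD-to-temperature cross-calibration, GLS trend fits with
#' bootstrap SEs, net environmental lag).
#'
#' Every random draw flows from one seed: the pipeline seeds the RNG once
#' and draws one sub-seed per stage, so partial re-runs are reproducible.
#' A stage failure aborts with the failing stage named; outputs of completed
#' stages are retained in `out_dir`.
#'
#' @param config a `scenario_config` for a synthetic run, or `NULL` to load
#'   CSV tables from `data_dir`.
#' @param data_dir directory of CSV tables (see [load_dataset()]).
#' @param out_dir optional output directory; stage outputs (CSV/JSON) and a
#'   machine-readable manifest are written there.
#' @param k,metric,cluster_method classification options.
#' @param a_max maximum WA-PLS components.
#' @param min_occ drop taxa with fewer than this many occurrences in the
#'   calibration window before fitting the transfer functions.
#' @param deshrink deshrinking convention for the transfer functions;
#'   `"classical"` (default) preserves reconstruction amplitude, which is
#'   what lag estimation needs (see [fit_wapls()]).
#' @param loo_tol cv R-squared tolerance of the component-selection
#'   parsimony rule; the pipeline default 0 selects the cv-optimal count,
#'   because under-fitting the composition-environment map leaves a
#'   systematic residual that drifts with the gradient and biases the lag.
#' @param calib_years calibration window (default: first two years).
#' @param base_year lag anchor year (default: first year).
#' @param n_boot bootstrap resamples for lag SEs and trend SEs.
#' @param prevalence_boot bootstrap resamples for the prevalence CIs; 0
#'   gives point estimates without CIs, a negative value skips the
#'   prevalence model entirely (the labels are still produced).
#' @param upland_cutoff altitude (m) dividing upland from lowland strata.
#' @param min_months,radius_km preprocessing parameters.
#' @param seed integer master seed (default: `config$seed`).
#' @return a list with each stage's outputs.
#' @export
run_pipeline <- function(config = NULL, data_dir = NULL, out_dir = NULL,
                         k = 3, metric = "jaccard", cluster_method = "ward",
                         a_max = 5, min_occ = 10, deshrink = "classical",
                         loo_tol = 0, calib_years = NULL, base_year = NULL,
                         n_boot = 400, prevalence_boot = 0,
                         upland_cutoff = 250, min_months = 9, radius_km = 25,
                         seed = NULL) {
  if (is.null(config) && is.null(data_dir))
    stop("provide a scenario config or a data directory")
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1, 6)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(out_dir) && is.data.frame(df))
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  data <- run_stage("input", {
    if (!is.null(config)) {
      scen <- simulate_scenario(config)
      list(y = scen$community$y, sample_info = scen$community$samples,
           sites = scen$sites, monthly = scen$monthly,
           discharge = scen$discharge,
           chem_xy = rbind(scen$chem_sites[c("site_id", "x", "y")]),
           scenario = scen)
    } else {
      d <- load_dataset(data_dir, seed = stage_seed[1])
      if (!nrow(d$monthly)) stop("chemistry table is empty")
      list(y = d$y, sample_info = d$sample_info, sites = d$sites,
           monthly = d$monthly, discharge = d$discharge,
           chem_xy = d$chem_sites, scenario = NULL)
    }
  })

  pre <- run_stage("preprocess", {
    set.seed(stage_seed[2])
    if (!nrow(data$monthly)) stop("chemistry table is missing or empty")
    build_annual_env(data$monthly, data$discharge, data$chem_xy,
                     data$sites, min_months = min_months,
                     radius_km = radius_km)
  })
  emit("annual_env", pre$annual_env)

  cls <- run_stage("classify", {
    set.seed(stage_seed[3])
    d <- dissimilarity(data$y, metric = metric)
    raw <- cluster_communities(d, k = k, method = cluster_method,
                               seed = stage_seed[3])
    env_key <- paste(pre$annual_env$site_id, pre$annual_env$year)
    samp_key <- paste(data$sample_info$site_id, data$sample_info$year)
    bod_at_sample <- pre$annual_env$bod[match(samp_key, env_key)]
    ordered <- order_classes(raw, bod_at_sample)
    labels <- cbind(data$sample_info, class = ordered$labels)
    prev <- if (prevalence_boot >= 0)
      prevalence_trends(labels, data$sites, n_boot = prevalence_boot,
                        seed = stage_seed[3]) else NULL
    list(labels = labels, class_bod = ordered$class_bod, prevalence = prev,
         bod_at_sample = bod_at_sample)
  })
  emit("labels", cls$labels)
  emit("prevalence", cls$prevalence)

  mk <- run_stage("markov", {
    strata <- stats::setNames(
      ifelse(data$sites$altitude > upland_cutoff, "upland", "lowland"),
      data$sites$site_id)
    tally <- tally_transitions(cls$labels, k = k, strata = strata)
    hier <- fit_loglinear_hierarchy(tally)
    P <- estimate_matrices(tally)
    obs_prev <- prop.table(table(factor(cls$labels$year),
                                 factor(cls$labels$class, levels = 1:k)), 1)
    obs_mat <- as.matrix(obs_prev)[as.character(tally$years), , drop = FALSE]
    stab <- stability_summary(P, observed = obs_mat)
    list(tally = tally, loglinear = hier, matrices = P, stability = stab)
  })
  emit("stability", mk$stability)
  emit("loglinear", mk$loglinear$table)

  tr <- run_stage("transfer", {
    set.seed(stage_seed[4])
    if (is.null(calib_years)) {
      yrs <- sort(unique(data$sample_info$year))
      calib_years <- yrs[1:2]
    }
    env_key <- paste(pre$annual_env$site_id, pre$annual_env$year)
    samp_key <- paste(data$sample_info$site_id, data$sample_info$year)
    obs_t <- pre$annual_env$temperature[match(samp_key, env_key)]
    obs_b <- log(pre$annual_env$bod[match(samp_key, env_key)])
    in_cal <- data$sample_info$year %in% calib_years
    fit_one <- function(x) {
      ok <- in_cal & is.finite(x)
      sel <- loo_select(data$y[ok, , drop = FALSE], x[ok], a_max = a_max,
                        tol = loo_tol, min_occ = min_occ, deshrink = deshrink)
      fit <- suppressWarnings(fit_wapls(data$y[ok, , drop = FALSE], x[ok],
                                        a_max = sel$a, min_occ = min_occ,
                                        deshrink = deshrink))
      rec <- suppressWarnings(predict(fit, data$y, n_comp = sel$a))
      list(fit = fit, a = sel$a, cv_r2 = sel$r2, reconstructed = rec)
    }
    t_mod <- fit_one(obs_t)
    b_mod <- fit_one(obs_b)
    nutr <- log(as.matrix(pre$annual_env[c("orthophosphate", "nitrate",
                                           "runoff")]))
    pc <- if (all(colSums(is.finite(nutr)) > 10))
      pca_composite(nutr, orient = "nitrate") else NULL
    list(temperature = t_mod, bod = b_mod, nutrient_pc = pc,
         observed_t = obs_t, observed_b = obs_b, calib_years = calib_years)
  })

  dc <- run_stage("debt_credit", {
    set.seed(stage_seed[5])
    if (is.null(base_year)) base_year <- min(data$sample_info$year)
    d_t <- data.frame(year = data$sample_info$year, observed = tr$observed_t,
                      reconstructed = tr$temperature$reconstructed)
    d_b <- data.frame(year = data$sample_info$year, observed = tr$observed_b,
                      reconstructed = tr$bod$reconstructed)
    ann_t <- annual_series(d_t)
    ann_b <- annual_series(d_b)
    yrs <- intersect(ann_t$year, ann_b$year)
    ann_t <- ann_t[ann_t$year %in% yrs, ]; ann_b <- ann_b[ann_b$year %in% yrs, ]
    cal <- cross_calibrate(tr$temperature$reconstructed,
                           tr$bod$reconstructed)
    acct <- compute_debt_credit(ann_t, ann_b, cal$g, base_year = base_year,
                                n_boot = n_boot, seed = stage_seed[5])
    lag_t <- annual_lag_series(d_t, base_year = base_year, n_boot = n_boot,
                               seed = stage_seed[5])
    lag_b <- annual_lag_series(d_b, base_year = base_year, n_boot = n_boot,
                               seed = stage_seed[5] %% 1000 + 1)
    # propagate calibration uncertainty (shared across all predictions of a
    # replicate) into the per-year lag SE
    in_cal <- data$sample_info$year %in% tr$calib_years
    add_calib_se <- function(lag_df, x_obs, n_comp, off) {
      cb <- lag_calibration_boot(data$y, x_obs, data$sample_info$year,
                                 in_cal, n_comp = n_comp,
                                 base_year = base_year,
                                 n_boot = min(n_boot, 100),
                                 seed = stage_seed[5] + off,
                                 deshrink = deshrink)
      m <- match(lag_df$year, cb$year)
      lag_df$se_within <- lag_df$se
      lag_df$se_calib <- cb$se_calib[m]
      lag_df$se <- sqrt(lag_df$se_within^2 + lag_df$se_calib^2)
      lag_df$se[lag_df$year == base_year] <- 0
      lag_df
    }
    lag_t <- add_calib_se(lag_t, tr$observed_t, tr$temperature$a, 11)
    lag_b <- add_calib_se(lag_b, tr$observed_b, tr$bod$a, 12)
    # headline SEs: combine year-resampling (GLS bootstrap) with the
    # full-chain calibration bootstrap (transfer refits + cross-calibration)
    cb <- debt_credit_calibration_boot(
      data$y, tr$observed_t, tr$observed_b, data$sample_info$year, in_cal,
      a_t = tr$temperature$a, a_b = tr$bod$a, base_year = base_year,
      n_boot = min(n_boot, 60), seed = stage_seed[5] + 13,
      deshrink = deshrink)
    acct$debt_final_se <- sqrt(acct$debt_final_se^2 + cb$debt_se^2)
    acct$credit_final_se <- sqrt(acct$credit_final_se^2 + cb$credit_se^2)
    acct$calibration_boot <- cb
    list(annual_temperature = ann_t, annual_bod = ann_b,
         lag_temperature = lag_t, lag_bod = lag_b,
         cross_calibration = cal, accounting = acct)
  })
  emit("lag_series", dc$accounting$series)
  emit("lag_temperature", dc$lag_temperature)

  result <- list(data = data, preprocess = pre, classify = cls, markov = mk,
                 transfer = tr, debt_credit = dc,
                 seed = seed, stage_seeds = stage_seed)
  if (!is.null(out_dir)) {
    run_stage("manifest", {
      files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
      manifest <- list(
        package = "streamlag",
        version = as.character(utils::packageVersion("streamlag")),
        seed = seed, stage_seeds = stage_seed,
        options = list(k = k, metric = metric, cluster_method = cluster_method,
                       a_max = a_max, base_year = base_year,
                       n_boot = n_boot, radius_km = radius_km),
        config = if (!is.null(config)) unclass(config)["taxa" != names(unclass(config))] else NULL,
        hashes = as.list(tools::md5sum(files)),
        headline = list(
          debt_final = dc$accounting$debt_final,
          debt_final_se = dc$accounting$debt_final_se,
          credit_final = dc$accounting$credit_final,
          credit_final_se = dc$accounting$credit_final_se,
          net_final = dc$accounting$net_final,
          net_p_value = dc$accounting$net_fit$p_value,
          net_significant = dc$accounting$net_fit$p_value < 0.05
        )
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  result
}
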