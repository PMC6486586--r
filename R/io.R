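.schemas <- list(
  samples = c("sample_id", "site_id", "year", "taxon", "abundance"),
  sites = c("site_id", "x", "y", "altitude", "slope", "distance", "urban"),
  chem_sites = c("site_id", "x", "y"),
  chemistry = c("site_id", "window_year", "month", "determinand", "value",
                "censored"),
  discharge = c("site_id", "year", "discharge", "catchment_km2")
)

read_table_checked <- function(path, schema_name) {
  schema <- .schemas[[schema_name]]
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) {
    d <- as.data.frame(stats::setNames(rep(list(logical(0)), length(schema)),
                                       schema))
    return(d)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schema, names(d))
  if (length(missing))
    stop(sprintf("schema error in %s: missing mandatory column '%s'",
                 basename(path), missing[1]))
  extra <- setdiff(names(d), schema)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown columns %s", basename(path),
                    paste(extra, collapse = ", ")))
    d <- d[schema]
  }
  d
}

#' Load a tabular dataset from CSV files
#'
#' Reads the four long-format tables (biology samples, site attributes,
#' monthly chemistry, discharge), validates that each declares its
#' mandatory columns (a schema error names the first missing column),
#' ignores unknown columns with a warning, and resolves duplicate biology
#' samples for one site-year by a seeded random choice of one sample.
#'
#' @param dir directory containing `samples.csv`, `sites.csv`,
#'   `chemistry.csv`, `discharge.csv`; alternatively give `paths` directly.
#' @param paths optional named list/vector overriding individual paths.
#' @param seed seed for the duplicate-sample choice.
#' @return list with `samples` (long biology), `y` (samples x taxa midpoint
#'   matrix), `sample_info` (sample_id, site_id, year), `sites`, `monthly`
#'   and `discharge`.
#' @export
load_dataset <- function(dir = NULL, paths = NULL, seed = 1) {
  default <- c(samples = "samples.csv", sites = "sites.csv",
               chemistry = "chemistry.csv", discharge = "discharge.csv")
  p <- if (is.null(paths)) file.path(dir, default) else unlist(paths)[names(default)]
  names(p) <- names(default)
  samples <- read_table_checked(p[["samples"]], "samples")
  sites <- read_table_checked(p[["sites"]], "sites")
  monthly <- read_table_checked(p[["chemistry"]], "chemistry")
  discharge <- read_table_checked(p[["discharge"]], "discharge")
  # chemistry/gauging locations are a separate, optional table; when absent
  # the chemistry is assumed co-located with the biology sites
  chem_path <- if (is.null(paths)) file.path(dir, "chem_sites.csv")
  else unlist(paths)[["chem_sites"]]
  chem_sites <- if (!is.null(chem_path) && !is.na(chem_path) &&
                    file.exists(chem_path))
    read_table_checked(chem_path, "chem_sites")
  else sites[c("site_id", "x", "y")]
  if (nrow(samples)) {
    key <- unique(samples[c("sample_id", "site_id", "year")])
    dup <- duplicated(key[c("site_id", "year")]) |
      duplicated(key[c("site_id", "year")], fromLast = TRUE)
    if (any(dup)) {
      set.seed(seed)
      keep_ids <- unlist(lapply(split(key$sample_id[dup],
                                      paste(key$site_id[dup], key$year[dup])),
                                function(ids) sample(ids, 1)))
      drop_ids <- setdiff(key$sample_id[dup], keep_ids)
      samples <- samples[!samples$sample_id %in% drop_ids, ]
    }
  }
  wide <- long_to_matrix(samples)
  list(samples = samples, y = wide$y, sample_info = wide$info, sites = sites,
       chem_sites = chem_sites, monthly = monthly, discharge = discharge)
}

long_to_matrix <- function(samples) {
  if (!nrow(samples)) {
    return(list(y = matrix(0, 0, 0),
                info = data.frame(sample_id = character(0),
                                  site_id = character(0), year = integer(0))))
  }
  ids <- unique(samples$sample_id)
  taxa <- sort(unique(samples$taxon))
  y <- matrix(0, length(ids), length(taxa), dimnames = list(ids, taxa))
  y[cbind(match(samples$sample_id, ids), match(samples$taxon, taxa))] <-
    samples$abundance
  info <- unique(samples[c("sample_id", "site_id", "year")])
  info <- info[match(ids, info$sample_id), ]
  rownames(info) <- NULL
  list(y = y, info = info)
}

#' Write a synthetic scenario to the CSV schemas that [load_dataset()] reads
#'
#' @param scenario output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  com <- scenario$community
  long <- data.frame(
    sample_id = rep(com$samples$sample_id, times = ncol(com$y)),
    site_id = rep(com$samples$site_id, times = ncol(com$y)),
    year = rep(com$samples$year, times = ncol(com$y)),
    taxon = rep(colnames(com$y), each = nrow(com$y)),
    abundance = as.vector(com$y)
  )
  long <- long[long$abundance > 0, ]
  utils::write.csv(long, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(scenario$sites[.schemas$sites],
                   file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(scenario$chem_sites[.schemas$chem_sites],
                   file.path(dir, "chem_sites.csv"), row.names = FALSE)
  utils::write.csv(scenario$monthly, file.path(dir, "chemistry.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$discharge, file.path(dir, "discharge.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Censoring-aware annual medians of monthly chemistry
#'
#' Applies [annual_median()] per site, annual window and determinand:
#' site-years with fewer than `min_months` monthly samples are rejected,
#' heavily censored site-years are imputed by regression on order
#' statistics, and every retained value carries a provenance tag.
#'
#' @param monthly long chemistry table (`site_id`, `window_year`, `month`,
#'   `determinand`, `value`, `censored`).
#' @param min_months minimum monthly samples per site-year (default 9).
#' @return data frame site_id, year, determinand, value, provenance.
#' @export
annualize_chemistry <- function(monthly, min_months = 9) {
  if (!nrow(monthly)) {
    return(data.frame(site_id = character(0), year = integer(0),
                      determinand = character(0), value = numeric(0),
                      provenance = character(0)))
  }
  grp <- split(monthly, list(monthly$site_id, monthly$window_year,
                             monthly$determinand), drop = TRUE)
  out <- lapply(grp, function(g) {
    am <- annual_median(g$value, g$censored, min_months = min_months)
    if (am$status != "ok") return(NULL)
    data.frame(site_id = g$site_id[1], year = g$window_year[1],
               determinand = g$determinand[1], value = am$value,
               provenance = if (am$provenance == "ros") "ros-imputed"
               else "measured")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the annual environment table at the biology locations
#'
#' Completes the io stage: annualises the monthly chemistry, imputes
#' missing nitrate from total oxidised nitrogen via the paired calibration
#' regression, standardises discharge to runoff, and interpolates every
#' variable-year surface to the biological sampling locations by local
#' ordinary kriging (chemistry and runoff on the log scale, back-transformed
#' afterwards). Each interpolated cell carries the provenance tag "kriged";
#' cells that could not be interpolated (no observation within the
#' neighbourhood) stay `NA`.
#'
#' @param monthly,discharge long input tables (see [load_dataset()]).
#' @param chem_xy data frame `site_id`, `x`, `y` of the chemistry and
#'   gauging locations.
#' @param bio_sites data frame `site_id`, `x`, `y` of biology locations.
#' @param min_months,radius_km,nmax preprocessing parameters.
#' @return list with `annual_chem` (per chemistry site, with provenance),
#'   `nitrate_calibration` (slope, intercept, r_squared or NULL) and
#'   `annual_env` (site_id, year, temperature, bod, nitrate, orthophosphate,
#'   runoff at the biology locations, plus provenance columns).
#' @export
build_annual_env <- function(monthly, discharge, chem_xy, bio_sites,
                             min_months = 9, radius_km = 25, nmax = 16) {
  ann <- annualize_chemistry(monthly, min_months = min_months)
  nit_cal <- NULL
  if (any(ann$determinand == "ton")) {
    nit <- ann[ann$determinand == "nitrate", ]
    ton <- ann[ann$determinand == "ton", ]
    key_n <- paste(nit$site_id, nit$year); key_t <- paste(ton$site_id, ton$year)
    shared <- intersect(key_n, key_t)
    need <- ton[!key_t %in% key_n, ]
    if (length(shared) >= 10 && nrow(need)) {
      imp <- impute_nitrate(need$value, nit$value[match(shared, key_n)],
                            ton$value[match(shared, key_t)])
      nit_cal <- imp[c("slope", "intercept", "r_squared")]
      ann <- rbind(ann[ann$determinand != "ton", ],
                   data.frame(site_id = need$site_id, year = need$year,
                              determinand = "nitrate",
                              value = imp$nitrate, provenance = "ros-imputed"))
    } else {
      ann <- ann[ann$determinand != "ton", ]
    }
  }
  if (nrow(discharge)) {
    ann <- rbind(ann, data.frame(
      site_id = discharge$site_id, year = discharge$year,
      determinand = "runoff",
      value = standardize_discharge(discharge$discharge,
                                    discharge$catchment_km2),
      provenance = "measured"))
  }
  vars <- intersect(c("temperature", "bod", "nitrate", "orthophosphate",
                      "runoff"), unique(ann$determinand))
  log_vars <- setdiff(vars, "temperature")
  years <- sort(unique(ann$year))
  env <- expand.grid(site_id = bio_sites$site_id, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  targets <- as.matrix(bio_sites[match(env$site_id[env$year == years[1]],
                                       bio_sites$site_id), c("x", "y")])
  for (v in vars) {
    env[[v]] <- NA_real_
    for (yr in years) {
      obs <- ann[ann$determinand == v & ann$year == yr, ]
      if (!nrow(obs)) next
      xy <- chem_xy[match(obs$site_id, chem_xy$site_id), c("x", "y")]
      ok <- stats::complete.cases(xy) & is.finite(obs$value) &
        (!(v %in% log_vars) | obs$value > 0)
      if (!any(ok)) next
      val <- if (v %in% log_vars) log(obs$value[ok]) else obs$value[ok]
      pred <- krige_local(targets, as.matrix(xy[ok, ]), val,
                          radius_km = radius_km, nmax = nmax)
      if (v %in% log_vars) pred <- exp(pred)
      env[[v]][env$year == yr] <- pred
    }
    env[[paste0("prov_", v)]] <- ifelse(is.finite(env[[v]]), "kriged",
                                        NA_character_)
  }
  list(annual_chem = ann, nitrate_calibration = nit_cal, annual_env = env)
}
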