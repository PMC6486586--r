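#' Pairwise dissimilarity between community samples
#'
#' Jaccard dissimilarity (1 - shared/union) on the presence-absence view, or
#' Bray-Curtis on abundance-class midpoints. A pair of empty samples has
#' undefined dissimilarity under both metrics; it is set to 0 with a
#' warning (two samples containing nothing are treated as identical).
#'
#' @param x samples x taxa matrix (midpoints or presence/absence).
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return a `dist` object with a `metric` attribute.
#' @export
dissimilarity <- function(x, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  d <- if (metric == "jaccard")
    vegan::vegdist(x > 0, method = "jaccard", binary = TRUE)
  else
    vegan::vegdist(x, method = "bray")
  if (any(!is.finite(d))) {
    warning("empty-sample pairs have undefined dissimilarity; set to 0")
    d[!is.finite(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}

#' Cluster samples into K community classes
#'
#' Partitions samples using either Ward's hierarchical method (on squared
#' dissimilarities, `hclust` method `ward.D2`) or partitioning around
#' medoids, both operating on a precomputed dissimilarity matrix.
#'
#' @param d `dist` object from [dissimilarity()].
#' @param k number of classes (typically 3, 5 or 7); must be < n.
#' @param method `"ward"` or `"pam"`.
#' @param seed integer seed (PAM medoid initialisation).
#' @return integer vector of class labels 1..k.
#' @export
cluster_communities <- function(d, k, method = c("ward", "pam"), seed = 1) {
  method <- match.arg(method)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 1) return(rep(1L, n))
  if (method == "ward") {
    unname(stats::cutree(stats::hclust(d, method = "ward.D2"), k = k))
  } else {
    set.seed(seed)
    as.integer(cluster::pam(d, k = k, diss = TRUE, cluster.only = TRUE))
  }
}

#' Order community classes along the pollution gradient
#'
#' Clustering labels are arbitrary; for interpretation as an ordered
#' sequence from clean to polluted, classes are relabelled in ascending
#' order of the mean observed BOD of their member samples, so class 1 holds
#' the communities of the cleanest (best-oxygenated) water and class K the
#' most polluted.
#'
#' @param labels integer class labels.
#' @param bod per-sample observed BOD (mg/l); needs >= 50% non-missing.
#' @return list with `labels` (relabelled), `map` (old -> new) and
#'   `class_bod` (mean BOD per new class).
#' @export
order_classes <- function(labels, bod) {
  stopifnot(length(labels) == length(bod))
  if (mean(is.finite(bod)) < 0.5) stop("BOD available for fewer than 50% of samples")
  means <- tapply(bod, labels, mean, na.rm = TRUE)
  ord <- order(means)                       # old labels sorted by mean BOD
  map <- integer(length(means))
  map[as.integer(names(means))[ord]] <- seq_along(ord)
  new_labels <- map[labels]
  list(labels = new_labels, map = map,
       class_bod = as.numeric(sort(means)))
}

#' Annual class prevalence with covariate adjustment and bootstrap CIs
#'
#' Estimates the national annual prevalence of each community class with a
#' per-class binomial GAM: logit P(class) ~ year-as-factor + log(1+altitude)
#' + log(1+slope) + log(1+distance from source) + log(1+urban fraction) + a
#' low-rank thin-plate spatial smooth of the site coordinates. Year enters
#' as a factor (annual transitions, not a smooth trend, are the object of
#' interest). Annual prevalence is the mean fitted probability over the
#' sites sampled that year; confidence limits come from a nonparametric
#' bootstrap that resamples sites (keeping all of a site's years together,
#' respecting repeated measures).
#'
#' @param samples data frame with `site_id`, `year`, `class`.
#' @param sites data frame with `site_id`, `x`, `y`, `altitude`, `slope`,
#'   `distance`, `urban`.
#' @param n_boot bootstrap resamples (default 400; 0 skips the CIs).
#' @param k_spatial basis dimension of the spatial smooth.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return data frame: class, year, prevalence, lower, upper.
#' @export
prevalence_trends <- function(samples, sites, n_boot = 400, k_spatial = 20,
                              seed = 1, conf = 0.95) {
  stopifnot(all(c("site_id", "year", "class") %in% names(samples)))
  d <- merge(samples, sites, by = "site_id")
  d$fyear <- factor(d$year)
  classes <- sort(unique(d$class))
  point <- prevalence_fit(d, classes, k_spatial)
  if (n_boot > 0) {
    set.seed(seed)
    site_ids <- unique(d$site_id)
    boots <- array(NA_real_, dim = c(n_boot, nrow(point)))
    for (b in seq_len(n_boot)) {
      take <- sample(site_ids, length(site_ids), replace = TRUE)
      idx <- unlist(lapply(take, function(s) which(d$site_id == s)))
      db <- d[idx, ]
      db$fyear <- factor(db$year, levels = levels(d$fyear))
      pb <- tryCatch(prevalence_fit(db, classes, k_spatial),
                     error = function(e) NULL)
      if (!is.null(pb))
        boots[b, ] <- pb$prevalence[match(paste(point$class, point$year),
                                          paste(pb$class, pb$year))]
    }
    a <- (1 - conf) / 2
    point$lower <- apply(boots, 2, stats::quantile, probs = a, na.rm = TRUE)
    point$upper <- apply(boots, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  } else {
    point$lower <- NA_real_; point$upper <- NA_real_
  }
  point
}

prevalence_fit <- function(d, classes, k_spatial) {
  out <- lapply(classes, function(cl) {
    d$yind <- as.integer(d$class == cl)
    fit <- mgcv::gam(
      yind ~ fyear + log1p(altitude) + log1p(slope) + log1p(distance) +
        log1p(urban) + s(x, y, bs = "tp", k = k_spatial),
      family = stats::binomial(), data = d, method = "GCV.Cp")
    p <- stats::fitted(fit)
    agg <- tapply(p, d$year, mean)
    data.frame(class = cl, year = as.integer(names(agg)),
               prevalence = as.numeric(agg), row.names = NULL)
  })
  do.call(rbind, out)
}
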