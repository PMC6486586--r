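#' Loglinear model hierarchy for transition counts
#'
#' Fits Poisson loglinear models to transition counts cross-classified by
#' state S, fate F, year T and river-type stratum R, to ask whether
#' transition probabilities are homogeneous in space and time, vary only in
#' time, only in space, in both additively, or with a full space-time
#' interaction. All candidate models contain the S:T:R margin so the
#' sampling design (row totals per year and stratum) is conditioned on;
#' what differs is how the fate distribution depends on T and R:
#'
#' \itemize{
#'   \item \code{SF}: fates depend on state only (homogeneous chain)
#'   \item \code{SFT}: fates vary through time
#'   \item \code{SFR}: fates vary between strata
#'   \item \code{SFT+SFR}: both, additively
#'   \item \code{SFTR}: full space-time interaction (saturated)
#' }
#'
#' Models are compared by AIC and likelihood-ratio tests of nested pairs;
#' the selected model is the simplest (fewest parameters) within
#' `aic_tol` AIC units of the minimum.
#'
#' @param tally a `transition_tally` from [tally_transitions()].
#' @param aic_tol AIC tolerance for the parsimony rule (default 2).
#' @return list with `table` (model, df, deviance, AIC, delta AIC), `lrt`
#'   (nested likelihood-ratio tests), `selected` (model name) and `fits`.
#' @export
fit_loglinear_hierarchy <- function(tally, aic_tol = 2) {
  stopifnot(inherits(tally, "transition_tally"))
  cnt <- tally$counts
  d <- expand.grid(T = factor(tally$years), S = factor(seq_len(tally$k)),
                   F = factor(seq_len(tally$k)), R = factor(tally$strata))
  d$count <- as.vector(cnt)
  # drop cells whose S x T x R margin is empty: no communities were at risk,
  # so the fate distribution there is not estimable
  margin <- stats::aggregate(count ~ S + T + R, d, sum)
  empty <- margin[margin$count == 0, c("S", "T", "R")]
  if (nrow(empty)) {
    warning(sprintf("dropping %d empty state-year-stratum margins", nrow(empty)))
    key <- paste(d$S, d$T, d$R)
    d <- d[!key %in% paste(empty$S, empty$T, empty$R), ]
  }
  multi_r <- length(tally$strata) > 1
  forms <- if (multi_r) list(
    "SF"      = count ~ S * T * R + S * F,
    "SFT"     = count ~ S * T * R + S * F * T,
    "SFR"     = count ~ S * T * R + S * F * R,
    "SFT+SFR" = count ~ S * T * R + S * F * T + S * F * R,
    "SFTR"    = count ~ S * F * T * R
  ) else list(
    "SF"  = count ~ S * T + S * F,
    "SFT" = count ~ S * F * T
  )
  fits <- lapply(forms, function(f)
    tryCatch(suppressWarnings(stats::glm(f, family = stats::poisson(),
                                         data = d,
                                         control = list(maxit = 50))),
             error = function(e) NULL))
  failed <- vapply(fits, is.null, TRUE)
  if (any(failed)) {
    warning(sprintf("loglinear fit failed for: %s",
                    paste(names(fits)[failed], collapse = ", ")))
    fits <- fits[!failed]
    if (!length(fits)) stop("all loglinear fits failed")
  }
  tab <- data.frame(
    model = names(fits),
    npar = vapply(fits, function(m) sum(!is.na(stats::coef(m))), 0),
    df = vapply(fits, stats::df.residual, 0),
    deviance = vapply(fits, stats::deviance, 0),
    aic = vapply(fits, stats::AIC, 0),
    row.names = NULL
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  nested <- if (multi_r) list(
    c("SF", "SFT"), c("SF", "SFR"), c("SFT", "SFT+SFR"),
    c("SFR", "SFT+SFR"), c("SFT+SFR", "SFTR")
  ) else list(c("SF", "SFT"))
  nested <- Filter(function(p) all(p %in% names(fits)), nested)
  lrt <- do.call(rbind, lapply(nested, function(p) {
    d0 <- stats::deviance(fits[[p[1]]]); d1 <- stats::deviance(fits[[p[2]]])
    df <- stats::df.residual(fits[[p[1]]]) - stats::df.residual(fits[[p[2]]])
    stat <- max(d0 - d1, 0)
    data.frame(null = p[1], alt = p[2], lr_stat = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }))
  within <- tab[tab$delta_aic <= aic_tol, ]
  selected <- within$model[which.min(within$npar)]
  list(table = tab, lrt = lrt, selected = selected, fits = fits)
}
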