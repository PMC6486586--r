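#' Tally annual class transitions from labelled site-year samples
#'
#' Builds the transition count array N[t, i, j] from class labels: for every
#' site, each pair of consecutive years in which the site was sampled
#' contributes one count from its class in year t (the state) to its class
#' in year t+1 (the fate). Sites without consecutive-year pairs contribute
#' nothing. An optional stratum (river type) per site adds a fourth axis.
#'
#' @param labels data frame with columns `site_id`, `year` (integer) and
#'   `class` (integer 1..K).
#' @param k number of classes; defaults to `max(labels$class)`.
#' @param strata optional named vector mapping site_id to stratum label.
#' @return object of class `transition_tally`: list with `counts` (array
#'   `[n_years-1, k, k]` or `[.., n_strata]`), `years` (the state years) and
#'   `strata` levels.
#' @export
tally_transitions <- function(labels, k = max(labels$class), strata = NULL) {
  stopifnot(all(c("site_id", "year", "class") %in% names(labels)))
  if (any(labels$year != round(labels$year))) stop("years must be integers")
  yrs <- seq(min(labels$year), max(labels$year) - 1L)
  if (!length(yrs)) stop("need at least two years")
  slev <- if (is.null(strata)) "all" else sort(unique(strata))
  counts <- array(0L, dim = c(length(yrs), k, k, length(slev)),
                  dimnames = list(year = yrs, state = seq_len(k),
                                  fate = seq_len(k), stratum = slev))
  key <- paste(labels$site_id, labels$year)
  cls <- labels$class[!duplicated(key)]
  names(cls) <- key[!duplicated(key)]
  for (s in unique(labels$site_id)) {
    st <- if (is.null(strata)) "all" else as.character(strata[[as.character(s)]])
    ys <- sort(unique(labels$year[labels$site_id == s]))
    pairs <- ys[(ys + 1L) %in% ys]
    for (y in pairs) {
      i <- cls[[paste(s, y)]]; j <- cls[[paste(s, y + 1L)]]
      counts[as.character(y), i, j, st] <- counts[as.character(y), i, j, st] + 1L
    }
  }
  structure(list(counts = counts, years = yrs, strata = slev, k = k),
            class = "transition_tally")
}

#' Maximum-likelihood annual transition matrices from a tally
#'
#' Each row of the year-t matrix is the multinomial MLE
#' \eqn{\hat p_{ij}(t) = N[t,i,j] / N[t,i,\cdot]}. Rows with zero total are
#' undefined and returned as `NA` (and reported via the `undefined`
#' attribute), never silently filled.
#'
#' @param tally a `transition_tally` (strata are summed over unless
#'   `stratum` selects one).
#' @param stratum optional stratum label to restrict to.
#' @return named list of K x K row-stochastic matrices, one per state year.
#' @export
estimate_matrices <- function(tally, stratum = NULL) {
  stopifnot(inherits(tally, "transition_tally"))
  cnt <- tally$counts
  cnt <- if (is.null(stratum)) apply(cnt, 1:3, sum) else
    cnt[, , , as.character(stratum), drop = FALSE][, , , 1]
  undefined <- character(0)
  out <- lapply(seq_along(tally$years), function(t) {
    N <- matrix(cnt[t, , ], tally$k, tally$k)
    tot <- rowSums(N)
    P <- N / ifelse(tot > 0, tot, NA_real_)
    if (any(tot == 0))
      undefined <<- c(undefined, paste0(tally$years[t], ":row", which(tot == 0)))
    P
  })
  names(out) <- tally$years
  attr(out, "undefined") <- undefined
  out
}

#' Stationary distribution of a transition matrix
#'
#' The equilibrium class-frequency distribution (the stationary community):
#' the unique left eigenvector w of a row-stochastic matrix with wP = w and
#' sum(w) = 1. Uniqueness requires an irreducible, aperiodic chain, which is
#' checked via the eigenvalue spectrum (exactly one eigenvalue on the unit
#' circle).
#'
#' @param P row-stochastic matrix.
#' @param tol tolerance for the unit-circle check.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(P, tol = 1e-8) {
  check_stochastic(P)
  ev <- eigen(t(P))
  on_circle <- abs(Mod(ev$values) - 1) < tol
  if (sum(on_circle) != 1)
    stop("no unique stationary distribution (chain reducible or periodic)")
  w <- Re(ev$vectors[, which.max(Mod(ev$values))])
  w <- w / sum(w)
  if (any(w < -tol)) stop("no unique stationary distribution (chain reducible or periodic)")
  pmax(w, 0) / sum(pmax(w, 0))
}

#' Damping ratio of a transition matrix
#'
#' The ratio of the dominant eigenvalue modulus to the second-largest
#' eigenvalue modulus, rho = lambda1 / |lambda2| (lambda1 = 1 for a
#' stochastic matrix). log(rho) is the asymptotic return rate to equilibrium
#' after a small perturbation, in units of per transition step. A rank-one
#' matrix (|lambda2| = 0) returns `Inf` for both.
#'
#' @param P row-stochastic matrix, K >= 2.
#' @return list with `rho` and `rate` (= log rho).
#' @export
damping_ratio <- function(P) {
  check_stochastic(P)
  if (nrow(P) < 2) stop("need at least two states")
  mods <- sort(Mod(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
  lam2 <- mods[2]
  rho <- if (lam2 < 1e-12) Inf else mods[1] / lam2
  list(rho = rho, rate = log(rho))
}

#' Dobrushin's ergodic coefficient
#'
#' alpha-bar = max over row pairs (i, j) of half the L1 distance between
#' rows i and j of P. It measures how fast two communities started in
#' different (non-equilibrium) states converge: the contraction factor per
#' step, with return rate -log(alpha-bar). alpha-bar = 1 means no guaranteed
#' contraction (e.g. the identity); identical rows give alpha-bar = 0 and an
#' infinite rate.
#'
#' @param P row-stochastic matrix.
#' @return list with `alpha` and `rate` (= -log alpha).
#' @export
dobrushin_coefficient <- function(P) {
  check_stochastic(P)
  k <- nrow(P)
  a <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    a <- max(a, 0.5 * sum(abs(P[i, ] - P[j, ])))
  list(alpha = a, rate = if (a < 1e-300) Inf else -log(a))
}

#' Proximity of observed class prevalence to equilibrium
#'
#' The mean absolute difference between observed class frequencies and the
#' stationary distribution; 0 when the community sits exactly at its
#' predicted equilibrium.
#'
#' @param observed,w probability vectors summing to 1.
#' @return scalar mean |observed - w|.
#' @export
equilibrium_proximity <- function(observed, w) {
  stopifnot(length(observed) == length(w))
  if (abs(sum(observed) - 1) > 1e-6 || abs(sum(w) - 1) > 1e-6)
    stop("both distributions must sum to 1")
  mean(abs(observed - w))
}

#' Per-year stability summary of a time-varying Markov chain
#'
#' For each annual transition matrix, computes the stationary community,
#' the persistence diagonal, the damping ratio and Dobrushin coefficient
#' with their return rates, and the proximity of the observed class
#' prevalence to equilibrium.
#'
#' @param P_list named list of annual transition matrices (NA-row matrices
#'   are skipped with `NA` outputs).
#' @param observed optional matrix (years x K) of observed class prevalence.
#' @return data frame, one row per year.
#' @export
stability_summary <- function(P_list, observed = NULL) {
  k <- nrow(P_list[[1]])
  rows <- lapply(seq_along(P_list), function(t) {
    P <- P_list[[t]]
    base <- data.frame(year = as.integer(names(P_list)[t]))
    if (any(!is.finite(P))) {
      base[c(paste0("w", seq_len(k)), paste0("persistence", seq_len(k)),
             "rho", "rate_rho", "alpha", "rate_alpha", "proximity")] <- NA_real_
      return(base)
    }
    w <- tryCatch(stationary_distribution(P), error = function(e) rep(NA_real_, k))
    dr <- damping_ratio(P); db <- dobrushin_coefficient(P)
    base[paste0("w", seq_len(k))] <- w
    base[paste0("persistence", seq_len(k))] <- diag(P)
    base$rho <- dr$rho; base$rate_rho <- dr$rate
    base$alpha <- db$alpha; base$rate_alpha <- db$rate
    base$proximity <- if (!is.null(observed) && !any(is.na(w)))
      equilibrium_proximity(observed[t, ], w) else NA_real_
    base
  })
  do.call(rbind, rows)
}

check_stochastic <- function(P, tol = 1e-8) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("P must be a square matrix")
  if (any(!is.finite(P)) || any(P < -tol) || any(abs(rowSums(P) - 1) > tol))
    stop("P must be row-stochastic")
  invisible(TRUE)
}
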