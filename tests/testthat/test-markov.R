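test_that("transition tallies count consecutive-year pairs only", {
  lab <- data.frame(site_id = c("A", "A", "A", "B", "B"),
                    year = c(1991L, 1992L, 1993L, 1991L, 1993L),
                    class = c(1L, 2L, 2L, 1L, 3L))
  tl <- tally_transitions(lab, k = 3)
  cnt <- apply(tl$counts, 1:3, sum)
  expect_equal(cnt["1991", 1, 2], 1)
  expect_equal(cnt["1992", 2, 2], 1)
  expect_equal(sum(cnt), 2)            # the gapped site contributes nothing
  # generator bookkeeping: total tally equals the number of consecutive
  # pairs actually present in the simulated record
  P <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  d <- simulate_markov_sequences(rep(list(P), 5), n_sites = 100,
                                 sampling_prob = 0.7, seed = 3)
  tl2 <- tally_transitions(d, k = 2)
  pairs <- sum(vapply(split(d$year, d$site_id), function(ys)
    sum((ys + 1L) %in% ys), 0))
  expect_equal(sum(tl2$counts), pairs)
})

test_that("matrix estimates are row-wise multinomial MLEs", {
  lab <- data.frame(
    site_id = rep(sprintf("s%02d", 1:10), each = 2),
    year = rep(c(1991L, 1992L), 10),
    class = c(rbind(rep(1L, 10), c(rep(1L, 8), 2L, 2L))))
  tl <- tally_transitions(lab, k = 3)
  P <- estimate_matrices(tl)[["1991"]]
  expect_equal(P[1, ], c(0.8, 0.2, 0))
  expect_true(all(is.na(P[2, ])))      # empty rows stay undefined
  expect_match(attr(estimate_matrices(tl), "undefined"), "row2", all = FALSE)
})

test_that("stationary distribution matches power iteration and rejects degeneracy", {
  # doubly stochastic: uniform by symmetry
  Pd <- matrix(c(0.5, 0.3, 0.2, 0.2, 0.5, 0.3, 0.3, 0.2, 0.5), 3, 3,
               byrow = TRUE)
  expect_equal(stationary_distribution(Pd), rep(1 / 3, 3), tolerance = 1e-12)
  P <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3, byrow = TRUE)
  expect_equal(stationary_distribution(P), stationary_power_oracle(P),
               tolerance = 1e-10)
  expect_error(stationary_distribution(diag(3)), "stationary")
  # periodic two-state flip has no limiting uniqueness in the aperiodic sense
  expect_error(stationary_distribution(matrix(c(0, 1, 1, 0), 2, 2)),
               "stationary")
  expect_error(stationary_distribution(matrix(c(0.5, 0.5, 0.4, 0.7), 2, 2,
                                              byrow = TRUE)), "row-stochastic")
})

test_that("damping ratio agrees with the characteristic-polynomial oracle", {
  expect_equal(damping_ratio(diag(3))$rho, 1)
  expect_equal(damping_ratio(diag(3))$rate, 0)
  rank1 <- matrix(c(0.2, 0.5, 0.3), 3, 3, byrow = TRUE)
  expect_equal(damping_ratio(rank1)$rho, Inf)
  expect_equal(damping_ratio(rank1)$rate, Inf)
  P <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3, byrow = TRUE)
  expect_equal(damping_ratio(P)$rho, damping_polyroot_oracle(P),
               tolerance = 1e-8)
})

test_that("Dobrushin coefficient equals the exhaustive pairwise computation", {
  expect_equal(dobrushin_coefficient(diag(3))$alpha, 1)
  expect_equal(dobrushin_coefficient(diag(3))$rate, 0)
  rows_same <- matrix(rep(c(0.2, 0.5, 0.3), 3), 3, 3, byrow = TRUE)
  expect_equal(dobrushin_coefficient(rows_same)$alpha, 0)
  expect_equal(dobrushin_coefficient(rows_same)$rate, Inf)
  P <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3, byrow = TRUE)
  expect_equal(dobrushin_coefficient(P)$alpha, 0.8)   # rows 1 vs 3
  expect_equal(dobrushin_coefficient(P)$alpha, dobrushin_oracle(P))
})

test_that("Dobrushin coefficient is sub-multiplicative", {
  set.seed(17)
  for (i in 1:25) {
    P <- random_stochastic(3); Q <- random_stochastic(3)
    expect_lte(dobrushin_coefficient(P %*% Q)$alpha,
               dobrushin_coefficient(P)$alpha *
                 dobrushin_coefficient(Q)$alpha + 1e-12)
  }
})

test_that("equilibrium proximity is a mean absolute difference", {
  w <- c(0.25, 0.5, 0.25)
  expect_equal(equilibrium_proximity(w, w), 0)
  expect_equal(equilibrium_proximity(c(1, 0, 0), c(0, 1, 0)), 2 / 3)
  expect_error(equilibrium_proximity(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  # LLN: frequencies of a chain at stationarity approach w
  P <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3, byrow = TRUE)
  w_true <- stationary_distribution(P)
  d <- simulate_markov_sequences(rep(list(P), 3), n_sites = 5000, seed = 23)
  obs <- as.numeric(prop.table(table(factor(d$class[d$year == 4], 1:3))))
  expect_lt(equilibrium_proximity(obs, w_true), 0.02)
})

test_that("matrix estimation error shrinks at the root-n rate", {
  P <- matrix(c(0.7, 0.2, 0.1, 0.15, 0.7, 0.15, 0.1, 0.2, 0.7), 3, 3,
              byrow = TRUE)
  sizes <- c(100, 1000, 10000)
  err <- vapply(seq_along(sizes), function(i) {
    d <- simulate_markov_sequences(list(P), n_sites = sizes[i],
                                   seed = 100 + i)
    Ph <- estimate_matrices(tally_transitions(d, k = 3))[[1]]
    sqrt(mean((Ph - P)^2))
  }, 0)
  slope <- coef(lm(log(err) ~ log(sizes)))[2]
  expect_lt(abs(slope + 0.5), 0.18)
})

test_that("loglinear hierarchy distinguishes homogeneous from time-varying chains", {
  # exactly proportional counts across years and strata: zero LR for the
  # time and stratum terms
  tl <- tally_transitions(data.frame(site_id = "x", year = 1991:1992,
                                     class = c(1L, 1L)), k = 2)
  base <- matrix(c(30, 10, 8, 32), 2, 2, byrow = TRUE)
  cnt <- array(0L, dim = c(3, 2, 2, 2))
  for (t in 1:3) for (r in 1:2) cnt[t, , , r] <- base * t * r
  tl$counts <- array(as.integer(cnt), dim = dim(cnt),
                     dimnames = list(year = 1991:1993, state = 1:2,
                                     fate = 1:2, stratum = c("a", "b")))
  tl$years <- 1991:1993; tl$strata <- c("a", "b"); tl$k <- 2
  h <- fit_loglinear_hierarchy(tl)
  expect_lt(h$lrt$lr_stat[h$lrt$alt == "SFT"], 1e-6)
  expect_lt(h$lrt$lr_stat[h$lrt$alt == "SFR"], 1e-6)
  expect_equal(h$selected, "SF")
  # homogeneous simulated chain: SF selected (single seed)
  P <- matrix(c(0.75, 0.15, 0.1, 0.1, 0.75, 0.15, 0.1, 0.15, 0.75), 3, 3,
              byrow = TRUE)
  d <- simulate_markov_sequences(rep(list(P), 10), n_sites = 500, seed = 61)
  strat <- setNames(rep(c("up", "low"), length.out = 500),
                    sprintf("S%04d", 1:500))
  h2 <- fit_loglinear_hierarchy(tally_transitions(d, k = 3, strata = strat))
  expect_equal(h2$selected, "SF")
  # chain with declining persistence of the polluted state (0.80 -> 0.35
  # over ten years, the water-quality-recovery signature): time model wins
  P_list <- lapply(0:9, function(t) {
    Pt <- P
    Pt[3, 3] <- 0.80 - 0.05 * t
    Pt[3, 1:2] <- Pt[3, 1:2] / sum(Pt[3, 1:2]) * (1 - Pt[3, 3])
    Pt
  })
  d3 <- simulate_markov_sequences(P_list, n_sites = 500, seed = 62)
  h3 <- fit_loglinear_hierarchy(tally_transitions(d3, k = 3, strata = strat))
  expect_true(h3$selected %in% c("SFT", "SFT+SFR", "SFTR"))
})

test_that("stability summary assembles the per-year diagnostics", {
  P <- matrix(c(0.8, 0.2, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8), 3, 3, byrow = TRUE)
  obs <- rbind(c(0.3, 0.4, 0.3), c(0.25, 0.5, 0.25))
  s <- stability_summary(list(`1991` = P, `1992` = P), observed = obs)
  expect_equal(nrow(s), 2)
  expect_equal(s$alpha, c(0.8, 0.8))
  expect_equal(s$persistence1, c(0.8, 0.8))
  expect_equal(s$proximity[2], 0, tolerance = 1e-10)
  expect_equal(s$w2, c(0.5, 0.5), tolerance = 1e-10)
})
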