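#!/usr/bin/env Rscript
# Stage 5: WA-PLS transfer functions calibrated on the 1991-1992 window
# (leave-one-out component selection), reconstruction of water temperature
# and log BOD for every sample, and the nutrient-discharge PCA composite.

suppressMessages(library(streamlag))

d <- load_dataset("results/data", seed = 1)
env <- read.csv("results/annual_env.csv")
key_e <- paste(env$site_id, env$year)
key_s <- paste(d$sample_info$site_id, d$sample_info$year)
obs_t <- env$temperature[match(key_s, key_e)]
obs_b <- log(env$bod[match(key_s, key_e)])

cal <- d$sample_info$year %in% 1991:1992
fit_target <- function(x, tag) {
  ok <- cal & is.finite(x)
  sel <- loo_select(d$y[ok, ], x[ok], a_max = 5, tol = 0, min_occ = 10,
                    deshrink = "classical")
  fit <- suppressWarnings(fit_wapls(d$y[ok, ], x[ok], a_max = sel$a,
                                    min_occ = 10, deshrink = "classical"))
  rec <- suppressWarnings(predict(fit, d$y))
  cat(sprintf("%s: %d component(s), cv R2 = %s\n", tag, sel$a,
              paste(sprintf("%.3f", sel$r2), collapse = " ")))
  list(rec = rec, a = sel$a)
}
t_mod <- fit_target(obs_t, "water temperature")
b_mod <- fit_target(obs_b, "log BOD")
rec_t <- t_mod$rec; rec_b <- b_mod$rec
jsonlite::write_json(list(a_temperature = t_mod$a, a_bod = b_mod$a),
                     "results/transfer_meta.json", auto_unbox = TRUE)

pc <- pca_composite(log(as.matrix(env[c("orthophosphate", "nitrate",
                                        "runoff")])), orient = "nitrate")
cat(sprintf("Nutrient-discharge PC1 explains %.0f%% of the variance.\n",
            100 * pc$var_fraction))

out <- data.frame(d$sample_info, observed_t = obs_t, reconstructed_t = rec_t,
                  observed_logbod = obs_b, reconstructed_logbod = rec_b)
write.csv(out, "results/reconstructions.csv", row.names = FALSE)
cat(sprintf("Reconstructed conditions for %d samples.\n", nrow(out)))
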