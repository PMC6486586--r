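#!/usr/bin/env Rscript
# Stage 4: annual transition matrices between the community classes, the
# loglinear test of spatio-temporal structure, and the stability of the
# chain (stationary community, persistence, damping ratio, Dobrushin
# coefficient, proximity to equilibrium).

suppressMessages(library(streamlag))

labels <- read.csv("results/labels.csv")
d <- load_dataset("results/data", seed = 1)

strata <- setNames(ifelse(d$sites$altitude > 250, "upland", "lowland"),
                   d$sites$site_id)
tl <- tally_transitions(labels, k = 3, strata = strata)
hier <- suppressWarnings(fit_loglinear_hierarchy(tl))
write.csv(hier$table, "results/loglinear.csv", row.names = FALSE)
write.csv(hier$lrt, "results/loglinear_lrt.csv", row.names = FALSE)

P <- estimate_matrices(tl)
obs <- prop.table(table(factor(labels$year), factor(labels$class, 1:3)), 1)
stab <- stability_summary(P, observed = as.matrix(obs)[as.character(tl$years), ])
write.csv(stab, "results/stability.csv", row.names = FALSE)
mats <- do.call(rbind, lapply(names(P), function(y)
  data.frame(year = y, state = rep(1:3, 3), fate = rep(1:3, each = 3),
             p = as.vector(P[[y]]))))
write.csv(mats, "results/transition_matrices.csv", row.names = FALSE)

cat(sprintf("Transitions tallied: %d; loglinear model selected: %s.\n",
            sum(tl$counts), hier$selected))
cat(sprintf("Mean persistence: %.2f / %.2f / %.2f.\n",
            mean(stab$persistence1, na.rm = TRUE),
            mean(stab$persistence2, na.rm = TRUE),
            mean(stab$persistence3, na.rm = TRUE)))
cat(sprintf("Mean return rates: log rho = %.2f, -log alpha = %.2f per yr;\n",
            mean(stab$rate_rho, na.rm = TRUE),
            mean(stab$rate_alpha[is.finite(stab$rate_alpha)], na.rm = TRUE)))
cat(sprintf("mean proximity to equilibrium: %.3f.\n",
            mean(stab$proximity, na.rm = TRUE)))
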