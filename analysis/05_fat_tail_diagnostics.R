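#!/usr/bin/env Rscript
# Detecting fat-tailedness from trajectory ensembles: log-log tail slopes
# over time, step-count (run-time proxy) distributions, and escape times of
# the explosive pure-growth system.
library(wildmoments)

out <- "results/fat_tail_diagnostics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

W <- run_ensemble(build_system("W"), x0 = 1, t_end = 5, n = 5000,
                  cap = 5000, base_seed = 5000)
P <- run_ensemble(build_system("P"), x0 = 1, t_end = 5, n = 5000,
                  cap = 10000, base_seed = 5000)

# tail slope of the fat-tailed system's empirical pmf, over time
times <- vapply(c(0.05, 0.5, 1, 2, 5),
                function(t) W$grid$points[which.min(abs(W$grid$points - t))],
                numeric(1))
tails <- do.call(rbind, lapply(times, function(t) {
  fit <- tail_exponent(empirical_pmf(W, t), k_lo = 1, k_hi = 20)
  data.frame(t = t, exponent = fit$exponent, se = fit$se,
             classification = fit$classification)
}))
write.csv(tails, file.path(out, "W_tail_exponents.csv"), row.names = FALSE)
print(tails, digits = 4)
cat("\nThe slope flattens with time toward the inverse-square reference (-2):\n")
cat("the distribution crosses from moment-having to fat-tailed.\n\n")
pmf_estimate_to_csv(empirical_pmf(W, 5), file.path(out, "W_pmf_t5.csv"))

# step-count statistics: the run-time proxy
sP <- step_stats(P, R = 175, x_star = 1)
sW <- step_stats(W, R = 175, x_star = 1)
write.csv(rbind(cbind(system = "P", as.data.frame(sP)),
                cbind(system = "W", as.data.frame(sW))),
          file.path(out, "step_stats.csv"), row.names = FALSE)
cat(sprintf("P: mean %.1f draws for 5 s; %.2f%% exceed 175 draws\n",
            sP$mean_steps, 100 * sP$frac_exceeding))
cat(sprintf("W: mean %.1f draws (uncapped, %d capped excluded); %.1f%% exceed 175;\n",
            sW$mean_steps, sW$n_excluded_mean, 100 * sW$frac_exceeding))
cat(sprintf("   %.1f%% rest at x = 1 at 5 s; odd draw counts %.1f%%\n",
            100 * sW$frac_final_at, 100 * sW$odd_fraction))
write.csv(data.frame(system = rep(c("P", "W"), c(P$n, W$n)),
                     draw_count = c(P$draw_counts, W$draw_counts),
                     capped = c(P$capped, W$capped)),
          file.path(out, "draw_counts.csv"), row.names = FALSE)

# escape times of the explosive system (cap 10 000 as escape proxy)
G <- run_ensemble(build_system("pure_growth"), x0 = 1, t_end = 50, n = 2000,
                  cap = 10000, base_seed = 7)
et <- escape_times(G)
write.csv(et, file.path(out, "escape_times.csv"), row.names = FALSE)
cat(sprintf(
  "\npure growth: mean escape time %.4f s (analytic limit pi^2/6 = %.4f)\n",
  mean(et$time[!et$censored]), pi^2 / 6))
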