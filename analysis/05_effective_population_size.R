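#!/usr/bin/env Rscript
# Stage 5: effective population size per Wright-Fisher population.
#
# Historical Ne from 30 x 50-kb LD bins via the Sved inversion (alpha
# = 1 here because the simulated populations carry no mutation),
# contemporary Ne from the bias-corrected LD method with the monogamy
# (non-random mating) model and pcrit = 0.05, a linear extrapolation
# of the recent trajectory to t = 1, and harmonic means per
# chromosome. The simulated truth is N = 100 throughout.

suppressMessages(library(popldne))
dir.create("results", showWarnings = FALSE)

summ <- NULL
for (pop in c("POPA", "POPB", "POPC")) {
  g <- apply_qc(read_vcf(sprintf("results/data/%s.vcf", pop),
                         pop = pop))$genotypes
  prs <- suppressMessages(pairwise_r2(g, estimator = "composite"))
  traj <- suppressMessages(historical_ne(prs, S = n_samples(g),
                                         settings = ne_settings(alpha = 1)))
  ctmp <- contemporary_ne_ld(g, mating = "monogamy", pcrit = 0.05)
  reg <- tryCatch(regress_contemporary(traj, t_max = 100),
                  error = function(e) NA_real_)
  message(sprintf(
    "%s: contemporary Ne %.0f [%.0f, %.0f], harmonic %.0f, regression %.0f",
    pop, ctmp$ne, ctmp$ci[1], ctmp$ci[2], traj$harmonic_overall, reg))
  write.table(traj$points, sprintf("results/ne_trajectory_%s.tsv", pop),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- rbind(summ, data.frame(
    population = pop, contemporary_ne = ctmp$ne,
    ci_low = ctmp$ci[1], ci_high = ctmp$ci[2],
    harmonic_ne = traj$harmonic_overall, regression_ne = reg,
    true_ne = 100))
}
write.table(summ, "results/ne_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
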