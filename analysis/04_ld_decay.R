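#!/usr/bin/env Rscript
# Stage 4: genome-wide linkage disequilibrium and its decay with
# distance, per Wright-Fisher population: all within-chromosome pairs
# up to 10 Mb, 100-kb decay bins, and the r2 > 0.8 extreme pairs.

suppressMessages(library(popldne))
dir.create("results", showWarnings = FALSE)

for (pop in c("POPA", "POPB", "POPC")) {
  g <- apply_qc(read_vcf(sprintf("results/data/%s.vcf", pop),
                         pop = pop))$genotypes
  prs <- suppressMessages(pairwise_r2(g, window_bp = 10e6,
                                      estimator = "em_haplotype"))
  dec <- bin_ld_decay(prs, bin_width = 100000, max_dist = 10e6)
  message(sprintf("%s: mean r2 %.3f +/- %.3f over %d pairs", pop,
                  dec$overall_mean, dec$overall_sd, dec$n_pairs))
  write.table(dec$bins, sprintf("results/ld_decay_%s.tsv", pop),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hi <- high_ld_pairs(prs, 0.80)
  message(sprintf("%s: %d pairs above r2 = 0.8", pop, nrow(hi)))
  write.table(hi, sprintf("results/ld_high_%s.tsv", pop),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
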