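#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study populations.
#
# The real farm genotypes behind this analysis are not public, so the
# whole workflow runs on simulated data with known truth:
#  * a three-population admixed SNP panel (Balding-Nichols divergence
#    F = 0.07, 3 x 55 fish, ~3K shared markers) for the structure
#    stages, and
#  * one Wright-Fisher population per breeding line (N = 100 diploids,
#    monogamous pairing, 4 x 40 Mb chromosomes at ~37 markers/Mb,
#    200 generations) for the LD and Ne stages.
# Everything is written as plain VCF plus truth sidecars under
# results/data/.

suppressMessages(library(popldne))
seed <- 20260920L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

message("three-population structure panel ...")
m <- 3000
adm <- simulate_admixed_genotypes(K = 3, F = 0.07, n = 165, m = m,
                                  seed = seed, group_sizes = c(55, 55, 55))
g <- adm$genotypes
g$variants$chrom <- rep(c("chr1", "chr2", "chr3"), length.out = m)
g$variants$pos <- as.integer(ceiling(seq_len(m) / 3) * 30000L)
# carry the population label inside the sample id so it survives the
# VCF round trip
g$samples$id <- sprintf("%s-%03d", g$samples$pop, seq_len(165))
g <- genotype_matrix(g$calls, g$variants, g$samples)
write_vcf(g, "results/data/structure_panel.vcf")
write_sim_truth(adm$truth, "results/data/structure_truth.tsv")

for (pop in c("POPA", "POPB", "POPC")) {
  message("Wright-Fisher population ", pop, " ...")
  wf <- simulate_wf_population(sim_config(
    n_individuals = 55, n_generations = 200,
    ne_trajectory = data.frame(generation = 1, N = 100),
    pop_label = pop, seed = seed + match(pop, c("POPA", "POPB", "POPC"))))
  write_vcf(wf$genotypes, sprintf("results/data/%s.vcf", pop))
  write_sim_truth(wf$truth[c("ne_trajectory", "founder_freqs")],
                  sprintf("results/data/%s_truth.tsv", pop))
}
message("done; inputs for stages 02-05 are under results/data/")
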