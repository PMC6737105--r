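#!/usr/bin/env Rscript
# Stage 3: population structure on the shared-marker panel.
#
# PCA of standardized genotypes (explained-variance fractions),
# observed/expected heterozygosity per population, pairwise
# Weir-Cockerham Fst, and maximum-likelihood admixture proportions
# with cross-validated choice of K.

suppressMessages(library(popldne))
dir.create("results", showWarnings = FALSE)

panel <- read_vcf("results/data/structure_panel.vcf")
panel$samples$pop <- sub("-.*$", "", panel$samples$id)
pops <- lapply(split_populations(panel), function(p)
  apply_qc(p)$genotypes)
pset <- intersect_markers(pops)
pops <- pset$populations
combined <- genotype_matrix(
  do.call(rbind, lapply(pops, `[[`, "calls")),
  pops[[1]]$variants,
  do.call(rbind, lapply(pops, `[[`, "samples")))

pc <- snp_pca(combined, k = 5)
message(sprintf("PC1 + PC2 explain %.1f%% of the variance",
                100 * sum(pc$explained_fraction[1:2])))
write.table(cbind(data.frame(sample = rownames(pc$coordinates),
                             pop = combined$samples$pop),
                  round(pc$coordinates, 4)),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

het <- lapply(pops, heterozygosity)
for (nm in names(het))
  message(sprintf("%s: Ho/He = %.2f/%.2f", nm, het[[nm]]$Ho, het[[nm]]$He))

prs <- combn(names(pops), 2, simplify = FALSE)
fst <- do.call(rbind, lapply(prs, function(pr) {
  f <- weir_cockerham_fst(pops[pr])
  message(sprintf("Fst %s vs %s: %.3f +/- %.2f (ratio of sums %.3f)",
                  pr[1], pr[2], f$mean_of_ratios, f$sd_theta, f$mean_theta))
  data.frame(pair = paste(pr, collapse = "_vs_"),
             fst_ratio_of_sums = f$mean_theta,
             fst_mean = f$mean_of_ratios, fst_sd = f$sd_theta)
}))
write.table(fst, "results/fst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cv <- select_k(combined, k_range = 1:5, folds = 3, seed = 7,
               max_iter = 300)
k_best <- cv$K[which.min(cv$cv_error)]
message("cross-validation favours K = ", k_best)
fit <- admixture_em(combined, K = k_best, seed = 7)
write.table(cbind(data.frame(sample = combined$samples$id,
                             pop = combined$samples$pop),
                  round(fit$Q, 4)),
            "results/admixture_Q.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cv, "results/admixture_cv.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
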