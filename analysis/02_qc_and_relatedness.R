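#!/usr/bin/env Rscript
# Stage 2: per-population genotype QC and relatedness.
#
# Markers failing MAF >= 0.05, exact HWE p >= 1e-6 or missingness
# <= 70% are removed within each population, samples below a 95% call
# rate are dropped, and the remaining marker sets are intersected so
# downstream stages see a common map. Pairwise identity-by-descent is
# estimated and reported; populations larger than 55 would be pruned
# here to a common size.

suppressMessages(library(popldne))
dir.create("results", showWarnings = FALSE)

panel <- read_vcf("results/data/structure_panel.vcf")
panel$samples$pop <- sub("-.*$", "", panel$samples$id)
pops <- split_populations(panel)
qc <- lapply(pops, apply_qc)
for (nm in names(qc)) {
  message(nm, ": ", qc[[nm]]$report$final_marker_count,
          " markers kept of ", n_variants(pops[[nm]]))
}
tab <- do.call(rbind, lapply(names(qc), function(nm) {
  r <- qc[[nm]]$report
  data.frame(population = nm, removed_by_maf = r$removed_by_maf,
             removed_by_hwe = r$removed_by_hwe,
             removed_by_callrate = r$removed_by_callrate,
             removed_other = r$removed_other,
             samples_removed = r$samples_removed,
             final_markers = r$final_marker_count)
}))
write.table(tab, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pset <- intersect_markers(lapply(qc, `[[`, "genotypes"))
message(pset$n_common, " markers shared across the three populations")

ib <- ibd_estimates(pset$populations[[1]])
message(sprintf("population %s mean pi_hat: %.3f +/- %.3f",
                names(pset$populations)[1], mean(ib$pi_hat), sd(ib$pi_hat)))
write.table(ib[, c("sample_i", "sample_j", "Z0", "Z1", "Z2", "pi_hat")],
            "results/ibd_pop1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
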