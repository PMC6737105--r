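#!/usr/bin/env Rscript
# Stage 6: marker requirements for genomic selection.
#
# From contemporary Ne and a genome length of L = 14.8 Morgans the
# effective number of chromosome segments is Me = 4 Ne L, and for
# unrelated individuals high-accuracy genomic prediction calls for
# about 2 Ne L individuals and 10 Ne L markers. Both the published
# contemporary Ne values for the three farmed tilapia lines
# (159 / 128 / 78) and this workflow's own simulated estimates are run
# through the arithmetic.

suppressMessages(library(popldne))
dir.create("results", showWarnings = FALSE)
L <- 14.8

published <- data.frame(population = c("POPA", "POPB", "POPC"),
                        ne = c(159, 128, 78))
own <- tryCatch(read.table("results/ne_summary.tsv", header = TRUE,
                           sep = "\t"),
                error = function(e) NULL)

rows <- lapply(seq_len(nrow(published)), function(i) {
  req <- marker_requirements(published$ne[i], L)
  data.frame(source = "published", population = published$population[i],
             ne = published$ne[i], me = req$Me_rounded,
             markers_10NeL = req$markers_10NeL_rounded,
             individuals_2NeL = req$individuals_2NeL_rounded)
})
if (!is.null(own)) {
  rows <- c(rows, lapply(seq_len(nrow(own)), function(i) {
    req <- marker_requirements(own$contemporary_ne[i], L)
    data.frame(source = "simulated", population = own$population[i],
               ne = own$contemporary_ne[i], me = req$Me_rounded,
               markers_10NeL = req$markers_10NeL_rounded,
               individuals_2NeL = req$individuals_2NeL_rounded)
  }))
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.table(tab, "results/marker_requirements.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("minimum Me from the published Ne: ",
        paste(tab$me[tab$source == "published"], collapse = " / "))
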