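Package: popldne
Title: Population Structure, Linkage Disequilibrium Decay and Effective
    Population Size from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic analysis of diploid biallelic
    SNP genotypes in farmed fish breeding populations: marker and sample
    quality control (minor allele frequency, exact Hardy-Weinberg test,
    call rate), method-of-moments identity-by-descent relatedness and
    pruning, principal component analysis, observed and expected
    heterozygosity, Weir-Cockerham Fst, maximum-likelihood admixture by
    EM with cross-validated choice of K, within-chromosome pairwise r2
    with distance-binned decay curves, and effective population size:
    historical Ne from binned LD via the Sved equation, contemporary Ne
    via the bias-corrected linkage-disequilibrium method, and derived
    marker-requirement calculations for genomic selection. Includes a
    forward-in-time Wright-Fisher simulator with recombination and a
    Balding-Nichols admixture generator so every stage is testable with
    known demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
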