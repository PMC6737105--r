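---
title: "Population structure, LD decay and effective population size: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure, LD decay and effective population size: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`popldne` implements the standard population-genomics workflow used to
characterise farmed fish breeding populations from dense SNP genotypes:
genotype quality control, relatedness pruning, population structure
(PCA, heterozygosity, Weir–Cockerham Fst, maximum-likelihood
admixture), within-chromosome linkage disequilibrium (LD) decay, and
LD-based effective population size (Ne) with the marker-requirement
arithmetic used to size genotyping panels for genomic selection. The
motivating setting is three Latin-American farmed Nile tilapia lines
descended from the admixed GIFT strain, genotyped on a ~50K SNP chip
and reduced to 55 fish and ~33K shared markers per population; because
such farm genotypes are proprietary, the package ships simulators that
reproduce that data shape with known truth, and every stage is
validated against simulated truth rather than against private data.

## The data model

All stages consume a `genotype_matrix`: an n × m matrix of diploid
alternate-allele dosages (0/1/2, `NA` for missing) with a variant map
(chromosome, 1-based bp position, alleles) and per-sample population
labels. Coordinates follow VCF conventions; inter-marker distance is
the absolute bp difference; chromosomes are opaque strings ordered by
first appearance. All statistics use pairwise-complete observations in
the presence of missing calls unless noted.

## Synthetic data with known truth

Two generators cover the two kinds of questions.

**Forward Wright–Fisher simulator** (`simulate_wf_population`).
Discrete non-overlapping generations of N diploids; each offspring
draws two parents — by default lifetime monogamous pairs re-formed each
generation, matching the non-random-mating model assumed later for
contemporary Ne — and receives gametes with Poisson(map length in
Morgans) crossovers at uniform positions. Defaults emulate the chip
data regime at desk scale: 4 chromosomes × 40 Mb at 37 markers/Mb
(≈1,500 markers per 40-Mb linkage group, the chip's density), 1 cM/Mb,
founder minor-allele frequencies Uniform(0.05, 0.5). Founders are drawn
site-independently, so LD builds up from zero by drift; recovery
analyses therefore run ≥ 2N generations of burn-in (200 at the default
N = 100) so that LD at the distances the Ne bins probe is close to
drift stationarity. There is no mutation and no selection during the
simulated epoch. Monomorphic loci are retained for QC to remove.

**Balding–Nichols admixture generator**
(`simulate_admixed_genotypes`). Source-population allele frequencies
are Beta-distributed around a common ancestral frequency
(Uniform(0.1, 0.9), keeping sources off the boundary) with variance
F p(1−p), so F is the expected Fst; ancestry rows are Dirichlet(α) (or
exact pure groups via `group_sizes`); genotypes are
Binomial(2, Σₖ QᵢₖPₖⱼ). Loci are unlinked, which is what makes this the
right null for Fst and admixture calibration and the wrong input for LD
stages.

What the simulators do **not** emulate: selection, assortative mating
beyond monogamy, genotyping error, batch effects, a real recombination
map (rates are uniform per chromosome), or the sigmoidal recombination
profile of real tilapia chromosomes. Passing recovery tests therefore
demonstrates correctness of the estimators under their own model
assumptions, not robustness to all features of real farm data.

## Quality control

`apply_qc` applies, in a fixed order: sample call rate ≥ 0.95, marker
missingness ≤ 0.70, MAF ≥ 0.05, exact Hardy–Weinberg p ≥ 1e-6. The
order matters only for attribution — each removed marker is charged to
the first criterion it fails, so the per-criterion counts partition the
removed set; the order is configurable because published QC tables
rarely state it. The HWE test is the exact conditional test (the
heterozygote count given allele counts; no mid-p), verified
exhaustively against an enumeration oracle for all tables with n ≤ 50.
QC is intended to run within each population separately; shared markers
are then intersected by (chromosome, position, alleles).

## Relatedness

`ibd_estimates` is the classic genome-wide method-of-moments IBD
estimator: per-pair IBS(0/1/2) counts combined with expected IBS-class
probabilities given IBD state, computed from in-sample allele
frequencies with the standard small-sample corrections (powers of p
replaced by unbiased products of allele counts). Raw Z probabilities
are clipped to [0, 1] and renormalised, raw values retained; note the
clipping makes the mean of `pi_hat` over truly unrelated pairs slightly
positive, so null checks should use the raw values. `prune_related` is
a deliberate heuristic — greedily drop the sample with the largest
summed pi_hat until the target size remains, ties broken by id — since
"exclude the highest-IBD animals" does not define an algorithm; it is
reported as greedy, not claimed optimal.

## Population structure

PCA standardises dosages by 2p̂ and √(2p̂(1−p̂)), drops monomorphic loci,
mean-imputes missing calls (flag results when missingness exceeds ~1%),
and eigendecomposes the sample-space Gram matrix; explained fractions
are eigenvalue/trace, identical to the locus-space covariance
eigenvalues.

Weir–Cockerham Fst uses the two-level variance components a, b, c with
unequal sample sizes. The headline estimate is the ratio of sums
Σa/Σ(a+b+c) — the estimator with good bias properties — while the mean
± SD of per-locus ratios is also reported, because per-locus dispersion
on SNP data is large and published values are often quoted in that
form. On Balding–Nichols simulations the ratio-of-sums mean brackets
the generating F across F ∈ {0.05, 0.1, 0.2}.

Admixture is the maximum-likelihood model — dosage
Binomial(2, Σₖ QᵢₖPₖⱼ) — fitted by EM from a seeded random start. This
deliberately replaces Bayesian MCMC clustering: same likelihood family,
deterministic given the seed, desk-scale; outputs are labelled
"admixture (ML)" so no posterior interpretation is implied. The EM
update is implemented as whole-matrix products (the responsibilities
enter only through row/column reductions), the log-likelihood is
non-decreasing by construction, and Q lives on the simplex at every
iteration. K is chosen by masked-genotype cross-validation: mask 5% of
non-missing calls, fit, score mean squared dosage error on the masked
calls; ancestry labels are only identified up to permutation, so
comparisons use `align_q_matrices`.

## Linkage disequilibrium

`pairwise_r2` computes all within-chromosome pairs up to a 10-Mb
window, with two estimators because the field's tools differ
internally: `em_haplotype` (two-locus haplotype frequencies from
unphased genotypes by EM, r² = D²/(p₁q₁p₂q₂); exact haplotype counting
when no double heterozygotes are present) and `composite` (squared
Pearson correlation of dosage vectors, equivalent to the Burrows
composite measure normalised by the HWE-departure-adjusted variances).
Decay curves default to `em_haplotype`; Ne estimation uses `composite`.
Under HWE at n = 55 the two agree within 0.02 on average. Decay curves
are arithmetic means over half-open 100-kb bins spanning 0–10 Mb; the
high-LD extraction uses strict r² > 0.80. A marker-count window cap is
not implemented: at chip densities the 10-Mb distance cap is the
binding constraint.

## Effective population size

**Historical trajectory** (`historical_ne`). LD at recombination
fraction c reflects Ne about t = 1/(2c) generations ago. Pairs are
grouped per chromosome into 30 bins of 50 kb (the defaults of the
standard chromosome-segment tool); each bin's mean r² is adjusted by
the literal r² − 1/S form (alternatives selectable), the bin midpoint
is converted to Morgans at 1 cM/Mb and mapped to c (identity by
default; Haldane and Sved–Feldman mappings available — Ne shifts with
this choice, so the mapping is echoed in the output), and the Sved
relation E[r²_adj] = 1/(α + 4 f(c) Ne) is inverted. Bins with fewer
than 50 pairs, non-positive adjusted LD, or implied non-positive Ne are
dropped with a log message. Per-chromosome trajectories are combined
per generation by harmonic mean, and both per-chromosome and overall
harmonic means are reported since published summaries are ambiguous
about which reduction they used.

The mutation adjustment α defaults to 2 — the "mutation present"
setting appropriate for real data and the published analyses. The
package's own recovery tests pass α = 1 instead: the Wright–Fisher
simulator deliberately contains no mutation, and using the
mutation-present constant on mutation-free truth biases every bin's Ne
low by construction (1/r² − 2 instead of 1/r² − 1). This is a
model-matching choice made once, not a tuning knob.

**Contemporary Ne** (`contemporary_ne_ld`). The bias-corrected LD
method: composite r² over locus pairs after screening alleles below
pcrit = 0.05, minus the published second-order sampling expectation
(1/S + 3.19/S² for S ≥ 30), converted to Ne with the published
constants — random mating (1/3 + √(1/9 − 2.76 r²'))/(2 r²'), lifetime
monogamy (2/3 + √(4/9 − 7.2 r²'))/(2 r²'), with the S < 30 variants —
the monogamy form being the "non-random mating" model. The constants
assume unlinked loci, so with more than one chromosome only
between-chromosome pairs are used (a single-chromosome panel falls
back to all pairs, which biases Ne down). Confidence intervals are a
delete-one-chromosome jackknife. Non-positive corrected r² yields an
infinite estimate, the method's standard signal that drift is
undetectable at that sample size.

**Extrapolation and requirements.** `regress_contemporary` fits OLS of
Ne on t over recent trajectory points (default t ≤ 100; the window is
a documented knob since published regressions rarely state theirs) and
predicts t = 1. `effective_segments` and `marker_requirements` give
Me = 4NeL, 10NeL markers and 2NeL individuals, raw and rounded to the
nearest hundred — the rounding convention that reproduces published
panel-size recommendations exactly (for L = 14.8 Morgans and Ne 159/
128/78: Me 9,400/7,600/4,600 and 11,500–23,500 markers).

## Numerical and design choices

* Seeds fix everything: both simulators consume a single integer seed,
  and pipeline stages derive sub-seeds from the configured seed.
* The EM estimators stop on log-likelihood (admixture, tol 1e-6, cap
  1000 iterations) or parameter change (haplotype EM, tol 1e-12); the
  admixture likelihood is clamped at 1e-12 from the boundary.
* Problem sizes in the tests and drivers are desk-scale by design:
  4 × 40 Mb chromosomes, ≤ 6K markers, N = 100, 20 replicate seeds for
  recovery checks — large enough that the estimators operate in their
  intended regime, small enough to run routinely.
* Monomorphic loci: dropped inside PCA, LD and IBD (uninformative);
  retained by the simulator; removed by QC's MAF filter.
* Degenerate inputs error early with specific messages (all-missing
  variants, infeasible two-locus D with the feasible range named,
  K > n, empty marker intersections, non-positive harmonic-mean
  inputs).

## Known limitations

* The contemporary-Ne sampling correction is the published one for the
  original composite estimator; with the Pearson-form composite used
  here it over-corrects slightly, and recovery medians run ~20–30%
  above truth at S = 50 — well inside the stochastic envelope of the
  method at these sample sizes.
* `prune_related` is greedy, not optimal; for pathological relatedness
  structures an optimal subset could differ.
* The admixture cross-validation error is nearly flat beyond the true
  K when divergence is weak, as for all such criteria; the selection is
  reported with its full error curve.
* No LD pruning is applied before PCA (matching the analysed datasets'
  practice); with strong local LD the leading components can pick up
  haplotype structure.
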