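test_that("the same seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_individuals = 12, n_chromosomes = 2,
                    chrom_length_bp = 5e6, marker_density = 10,
                    ne_trajectory = data.frame(generation = 1, N = 20),
                    n_generations = 15, seed = 99)
  a <- simulate_wf_population(cfg)
  b <- simulate_wf_population(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth$founder_freqs, b$truth$founder_freqs)
  cfg2 <- cfg; cfg2$seed <- 100L
  c <- simulate_wf_population(cfg2)
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
})

test_that("genotype values stay in {0,1,2,NA} and missing injection works", {
  cfg <- sim_config(n_individuals = 20, n_chromosomes = 1,
                    chrom_length_bp = 4e6, marker_density = 25,
                    ne_trajectory = data.frame(generation = 1, N = 30),
                    n_generations = 10, missing_rate = 0.1, seed = 5)
  g <- simulate_wf_population(cfg)$genotypes
  expect_true(all(g$calls %in% c(0L, 1L, 2L, NA)))
  expect_gt(mean(is.na(g$calls)), 0.05)
  expect_lt(mean(is.na(g$calls)), 0.15)
})

test_that("without recombination whole chromosomes descend as blocks", {
  cfg <- sim_config(n_individuals = 10, n_chromosomes = 1,
                    chrom_length_bp = 5e6, marker_density = 10,
                    recomb_rate = 0,
                    ne_trajectory = data.frame(generation = 1, N = 10),
                    n_generations = 60, seed = 6)
  g <- simulate_wf_population(cfg)$genotypes
  poly <- which(apply(g$calls, 2, function(x) length(unique(x))) > 1)
  expect_gt(length(poly), 2)
  cm <- suppressWarnings(cor(g$calls[, poly]))^2
  expect_true(all(abs(cm[upper.tri(cm)] - 1) < 1e-12))
})

test_that("neutral allele frequencies are conserved in expectation", {
  diffs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_individuals = 40, n_chromosomes = 1,
                      chrom_length_bp = 4e6, marker_density = 25,
                      ne_trajectory = data.frame(generation = 1, N = 40),
                      n_generations = 10, seed = 200 + s)
    sim <- simulate_wf_population(cfg)
    mean(alt_freqs(sim$genotypes) - sim$truth$founder_freqs)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.01)
})

test_that("expected heterozygosity decays at about (1 - 1/2N) per generation", {
  ratios <- vapply(1:6, function(s) {
    cfg <- sim_config(n_individuals = 50, n_chromosomes = 2,
                      chrom_length_bp = 5e6, marker_density = 20,
                      ne_trajectory = data.frame(generation = 1, N = 50),
                      n_generations = 60, seed = 300 + s)
    sim <- simulate_wf_population(cfg)
    p0 <- sim$truth$founder_freqs
    p1 <- alt_freqs(sim$genotypes)
    mean(2 * p1 * (1 - p1)) / mean(2 * p0 * (1 - p0))
  }, numeric(1))
  expected <- (1 - 1 / (2 * 50))^60
  expect_lt(abs(mean(ratios) - expected) / expected, 0.15)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(ne_trajectory = data.frame(generation = 1, N = 1)),
               "N values must be >= 2")
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e4,
                    marker_density = 1, n_generations = 2)
  expect_error(simulate_wf_population(cfg), "zero markers")
})

test_that("admixture truth rows live on the simplex and pure groups separate", {
  sim <- simulate_admixed_genotypes(K = 3, F = 0.1, alpha = 0.5, n = 40,
                                    m = 300, seed = 2)
  expect_equal(rowSums(sim$truth$Q), rep(1, 40), tolerance = 1e-12)
  expect_true(all(sim$truth$P >= 0 & sim$truth$P <= 1))
  expect_error(simulate_admixed_genotypes(K = 2, alpha = 0, n = 10, m = 10),
               "alpha")
  # K = 1: two arbitrary halves are undifferentiated
  one <- simulate_admixed_genotypes(K = 1, F = 0, n = 60, m = 3000, seed = 9)
  g <- one$genotypes
  g$samples$pop <- rep(c("H1", "H2"), each = 30)
  fst <- weir_cockerham_fst(g)
  expect_lt(abs(fst$mean_theta), 0.01)
})

test_that("two-locus samples follow the requested disequilibrium", {
  # complete association: only two haplotype classes
  tl <- make_two_locus_sample(0.5, 0.5, 0.25, 200, seed = 1)
  hap <- attr(tl, "haplotypes")
  expect_setequal(unique(paste(hap[, 1], hap[, 2])), c("1 1", "0 0"))
  expect_equal(hap_count_r2(hap[, 1], hap[, 2]), 1)
  # closed form D^2 / (p1 q1 p2 q2) at D = 0.1
  r2s <- vapply(1:10, function(s) {
    x <- make_two_locus_sample(0.5, 0.5, 0.1, 4000, seed = s)
    pairwise_r2(x, estimator = "em_haplotype")$r2
  }, numeric(1))
  expect_equal(mean(r2s), 0.16, tolerance = 0.05)
  # linkage equilibrium
  tl0 <- make_two_locus_sample(0.3, 0.6, 0, 8000, seed = 4)
  expect_lt(pairwise_r2(tl0, estimator = "composite")$r2, 0.005)
  # infeasible D names the feasible range
  expect_error(make_two_locus_sample(0.1, 0.1, 0.5, 10),
               "feasible range")
})
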