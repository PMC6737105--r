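# Fixture builders and independent oracles used across the suite.

# tiny genotype matrix on one chromosome with evenly spaced positions
make_gm <- function(calls, chrom = NULL, pos = NULL, pop = "P1") {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = pos,
                             id = sprintf("v%03d", seq_len(m)),
                             ref = "A", alt = "C"),
                  data.frame(id = sprintf("s%03d", seq_len(nrow(calls))),
                             pop = rep_len(pop, nrow(calls))))
}

# genotypes drawn under Hardy-Weinberg at given alt frequencies
hwe_genotypes <- function(n, freqs, seed) {
  set.seed(seed)
  m <- length(freqs)
  matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
}

# full-sib families with independent loci: parents drawn from HWE,
# each parent transmits one allele per locus per child
sib_genotypes <- function(n_families, kids_per_family, freqs, seed) {
  set.seed(seed)
  m <- length(freqs)
  draw_parent <- function() cbind(stats::rbinom(m, 1L, freqs),
                                  stats::rbinom(m, 1L, freqs))
  calls <- NULL
  fam <- integer(0)
  for (f in seq_len(n_families)) {
    pa <- draw_parent(); pb <- draw_parent()
    for (k in seq_len(kids_per_family)) {
      ga <- pa[cbind(seq_len(m), sample(1:2, m, replace = TRUE))]
      gb <- pb[cbind(seq_len(m), sample(1:2, m, replace = TRUE))]
      calls <- rbind(calls, ga + gb)
      fam <- c(fam, f)
    }
  }
  list(gm = make_gm(calls), family = fam)
}

# exact-HWE conditional distribution computed from first principles:
# direct product formula per heterozygote count, no shared code with
# the package implementation (plain factorials, no log-space trick)
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  prob_of <- function(h) {
    naa_h <- (nA - h) / 2
    nbb_h <- (na - h) / 2
    exp(lgamma(n + 1) - lgamma(naa_h + 1) - lgamma(h + 1) -
          lgamma(nbb_h + 1) + h * log(2) +
          lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1))
  }
  probs <- vapply(hs, prob_of, numeric(1))
  p_obs <- prob_of(n_Aa)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# literal step-by-step transcription of the two-population
# variance-components formulas for one biallelic locus
wc_oracle_single_locus <- function(g1, g2) {
  n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
  p1 <- sum(g1, na.rm = TRUE) / (2 * n1)
  p2 <- sum(g2, na.rm = TRUE) / (2 * n2)
  h1 <- sum(g1 == 1, na.rm = TRUE) / n1
  h2 <- sum(g2 == 1, na.rm = TRUE) / n2
  r <- 2
  n_bar <- (n1 + n2) / r
  C2 <- ((n1 - n_bar)^2 + (n2 - n_bar)^2) / ((r - 1) * n_bar^2)
  n_c <- n_bar * (1 - C2 / r)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# r2 from known phased haplotypes by direct counting
hap_count_r2 <- function(hapA, hapB) {
  n <- length(hapA)
  p11 <- mean(hapA == 1 & hapB == 1)
  pA <- mean(hapA); pB <- mean(hapB)
  D <- p11 - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# standard recovery-test WF run shared by several suites
quick_wf <- function(seed, N = 100, n_ind = 50, gens = 200,
                     density = 37, chroms = 4, monogamy = TRUE) {
  cfg <- sim_config(n_individuals = n_ind, n_chromosomes = chroms,
                    chrom_length_bp = 40e6, marker_density = density,
                    ne_trajectory = data.frame(generation = 1, N = N),
                    n_generations = gens, monogamy = monogamy, seed = seed)
  simulate_wf_population(cfg)
}
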