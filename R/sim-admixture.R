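#' Simulate admixed genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies for each of `K` source populations are
#' drawn Balding-Nichols around a common ancestral frequency: for
#' ancestral frequency p and divergence F, the source frequency is
#' Beta(p (1 - F) / F, (1 - p)(1 - F) / F), which has mean p and
#' variance F p (1 - p) (so F is the expected Fst of the sources).
#' Individual ancestry rows are Dirichlet(alpha), and the genotype at
#' locus j for sample i is Binomial(2, sum_k Q_ik P_kj).
#'
#' @param K Number of ancestral source populations.
#' @param F Divergence parameter in [0, 1), scalar or length `K`.
#' @param alpha Dirichlet concentration (> 0), scalar or length `K`.
#'   Small values give near-pure individuals.
#' @param n Number of diploid samples.
#' @param m Number of markers.
#' @param seed Integer seed.
#' @param group_sizes Optional integer vector of length `K`; when given,
#'   `Q` is an exact block indicator (pure groups of these sizes,
#'   summing to `n`) instead of Dirichlet draws.
#' @param anc_freq_range Range of the uniform common ancestral
#'   frequency (default 0.1-0.9, keeping sources away from fixation).
#' @return List with `genotypes` (a [genotype_matrix()], population
#'   labels by largest ancestry fraction) and `truth` (list with `Q`
#'   n x K, `P` K x m, `F`, `anc_freqs`).
#' @export
simulate_admixed_genotypes <- function(K, F = 0.1, alpha = 1, n = 100,
                                       m = 1000, seed = 1L,
                                       group_sizes = NULL,
                                       anc_freq_range = c(0.1, 0.9)) {
  stopifnot(K >= 1, m >= 1, n >= 1)
  F <- rep_len(F, K)
  if (any(F < 0) || any(F >= 1)) stop("F must be in [0, 1)")
  if (is.null(group_sizes) && any(alpha <= 0)) stop("alpha must be > 0")
  set.seed(as.integer(seed))

  p_anc <- stats::runif(m, anc_freq_range[1], anc_freq_range[2])
  P <- matrix(0, nrow = K, ncol = m)
  for (k in seq_len(K)) {
    if (F[k] == 0) {
      P[k, ] <- p_anc
    } else {
      shape_scale <- (1 - F[k]) / F[k]
      P[k, ] <- stats::rbeta(m, p_anc * shape_scale,
                             (1 - p_anc) * shape_scale)
    }
  }

  if (!is.null(group_sizes)) {
    stopifnot(length(group_sizes) == K, sum(group_sizes) == n)
    Q <- matrix(0, nrow = n, ncol = K)
    grp <- rep(seq_len(K), group_sizes)
    Q[cbind(seq_len(n), grp)] <- 1
  } else {
    a <- rep_len(alpha, K)
    G <- matrix(stats::rgamma(n * K, shape = rep(a, each = n)),
                nrow = n, ncol = K)
    rs <- rowSums(G)
    # numerically degenerate rows (all gamma draws underflow): assign a
    # random vertex so rows always sum to 1
    zero <- rs == 0
    if (any(zero)) {
      G[zero, ] <- 0
      G[cbind(which(zero), sample.int(K, sum(zero), replace = TRUE))] <- 1
      rs[zero] <- 1
    }
    Q <- G / rs
  }

  expfreq <- Q %*% P
  calls <- matrix(stats::rbinom(n * m, 2L, as.vector(expfreq)),
                  nrow = n, ncol = m)
  pop <- sprintf("K%d", max.col(Q, ties.method = "first"))
  variants <- data.frame(chrom = "chr1", pos = seq_len(m) * 1000L,
                         id = sprintf("snp%05d", seq_len(m)),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("adm_%04d", seq_len(n)), pop = pop,
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, variants, samples)
  list(genotypes = gm,
       truth = list(Q = Q, P = P, F = F, anc_freqs = p_anc))
}

#' Exact two-locus sample with a specified disequilibrium coefficient
#'
#' Draws `2n` haplotypes from the exact two-locus haplotype distribution
#' implied by allele frequencies `pA`, `pB` and disequilibrium `D`
#' (haplotype frequencies pA pB + D, pA qB - D, qA pB - D, qA qB + D)
#' and pairs them at random into `n` diploids. The underlying haplotypes
#' are attached as attribute `"haplotypes"` so phase-aware oracles can
#' use them.
#'
#' @param pA,pB Allele frequencies of the counted (alt) allele at the
#'   two loci.
#' @param D Disequilibrium coefficient; must keep all four haplotype
#'   frequencies in [0, 1].
#' @param n Number of diploid samples.
#' @param seed Integer seed.
#' @param positions Base-pair positions of the two loci on one
#'   chromosome (default 10 kb apart).
#' @return A [genotype_matrix()] with two variants, with attribute
#'   `haplotypes` (a `2n` x 2 matrix of 0/1 allele states).
#' @export
make_two_locus_sample <- function(pA, pB, D, n, seed = 1L,
                                  positions = c(10000L, 20000L)) {
  qA <- 1 - pA; qB <- 1 - pB
  h <- c(AB = pA * pB + D, Ab = pA * qB - D, aB = qA * pB - D,
         ab = qA * qB + D)
  if (any(h < -1e-12) || any(h > 1 + 1e-12)) {
    lo <- max(-pA * pB, -qA * qB)
    hi <- min(pA * qB, qA * pB)
    stop(sprintf("infeasible D = %g for pA = %g, pB = %g; feasible range [%g, %g]",
                 D, pA, pB, lo, hi))
  }
  h <- pmax(h, 0); h <- h / sum(h)
  set.seed(as.integer(seed))
  cls <- sample.int(4L, 2L * n, replace = TRUE, prob = h)
  hapA <- c(1L, 1L, 0L, 0L)[cls]   # allele at locus A per haplotype
  hapB <- c(1L, 0L, 1L, 0L)[cls]
  i1 <- seq(1L, 2L * n, by = 2L); i2 <- i1 + 1L
  calls <- cbind(hapA[i1] + hapA[i2], hapB[i1] + hapB[i2])
  variants <- data.frame(chrom = "chr1", pos = as.integer(positions),
                         id = c("locusA", "locusB"),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("tl_%04d", seq_len(n)), pop = "SIM",
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, variants, samples)
  attr(gm, "haplotypes") <- cbind(A = hapA, B = hapB)
  gm
}
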