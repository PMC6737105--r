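#' Pairwise identity-by-descent estimates by method of moments
#'
#' The classic genome-wide IBD moments estimator: for every sample
#' pair, observed counts of loci identical-by-state for 0, 1 or 2
#' alleles are combined with the expected IBS-class probabilities given
#' IBD state 0/1/2 computed from in-sample allele frequencies. The
#' expectations use the standard small-sample corrections, replacing
#' powers of the allele frequency by unbiased products of allele
#' counts, e.g. p^2 q^2 -> X(X-1)Y(Y-1) / (T(T-1)(T-2)(T-3)) for X alt
#' and Y ref alleles out of T. Raw Z estimates outside [0, 1] are
#' clipped and renormalized; the raw values are retained.
#'
#' Monomorphic loci carry no IBD information and are dropped. Loci with
#' fewer than two called genotypes are dropped. With missing data,
#' every pair uses its pairwise-complete loci.
#'
#' @param x A [genotype_matrix()] with at least 2 samples.
#' @return Data frame of class `ibd_estimates` with columns `sample_i`,
#'   `sample_j`, `Z0`, `Z1`, `Z2`, `pi_hat`, `raw_Z0`, `raw_Z1`,
#'   `raw_Z2`, `n_loci`.
#' @export
ibd_estimates <- function(x) {
  n <- n_samples(x)
  if (n < 2L) stop("need at least 2 samples")
  G <- x$calls
  st <- per_marker_stats(G)
  keep <- st$n_called >= 2L & !is.na(st$maf) & st$maf > 0
  if (!any(keep)) stop("no polymorphic loci; IBD is undefined")
  G <- G[, keep, drop = FALSE]
  m <- ncol(G)

  # per-locus expected IBS-class probabilities given IBD state
  nc <- colSums(!is.na(G))
  X <- colSums(G, na.rm = TRUE)        # alt allele count
  Tt <- 2 * nc
  Y <- Tt - X
  d3 <- Tt * (Tt - 1) * (Tt - 2)
  d4 <- d3 * (Tt - 3)
  p2q2 <- X * (X - 1) * Y * (Y - 1) / d4
  p3q <- X * (X - 1) * (X - 2) * Y / d4
  pq3 <- X * Y * (Y - 1) * (Y - 2) / d4
  p4 <- X * (X - 1) * (X - 2) * (X - 3) / d4
  q4 <- Y * (Y - 1) * (Y - 2) * (Y - 3) / d4
  p2q <- X * (X - 1) * Y / d3
  pq2 <- X * Y * (Y - 1) / d3
  p3 <- X * (X - 1) * (X - 2) / d3
  q3 <- Y * (Y - 1) * (Y - 2) / d3
  e <- list(E00 = 2 * p2q2,
            E10 = 4 * p3q + 4 * pq3,
            E20 = p4 + q4 + 4 * p2q2,
            E11 = 2 * p2q + 2 * pq2,
            E21 = p3 + q3 + p2q + pq2,
            E22 = rep(1, m))

  # observed IBS class counts for all pairs via indicator crossproducts
  I0 <- (!is.na(G) & G == 0L) + 0
  I1 <- (!is.na(G) & G == 1L) + 0
  I2 <- (!is.na(G) & G == 2L) + 0
  N0 <- tcrossprod(I0, I2); N0 <- N0 + t(N0)
  A02 <- I0 + I2
  N1 <- tcrossprod(I1, A02); N1 <- N1 + t(N1)
  N2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)

  # expected sums over each pair's complete loci
  M <- is.na(G) + 0
  pair_sum <- function(ev) {
    tot <- sum(ev)
    if (!any(M > 0)) return(matrix(tot, n, n))
    mi <- as.vector(M %*% ev)
    both <- tcrossprod(sweep(M, 2L, ev, "*"), M)
    tot - outer(mi, rep(1, n)) - outer(rep(1, n), mi) + both
  }
  S00 <- pair_sum(e$E00); S10 <- pair_sum(e$E10); S20 <- pair_sum(e$E20)
  S11 <- pair_sum(e$E11); S21 <- pair_sum(e$E21); S22 <- pair_sum(e$E22)

  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  k <- cbind(i, j)
  z0 <- N0[k] / S00[k]
  z1 <- (N1[k] - z0 * S10[k]) / S11[k]
  z2 <- (N2[k] - z0 * S20[k] - z1 * S21[k]) / S22[k]
  raw <- cbind(z0, z1, z2)
  cl <- pmin(pmax(raw, 0), 1)
  cl <- cl / rowSums(cl)
  out <- data.frame(sample_i = x$samples$id[i], sample_j = x$samples$id[j],
                    Z0 = cl[, 1L], Z1 = cl[, 2L], Z2 = cl[, 3L],
                    pi_hat = cl[, 2L] / 2 + cl[, 3L],
                    raw_Z0 = raw[, 1L], raw_Z1 = raw[, 2L],
                    raw_Z2 = raw[, 3L],
                    n_loci = S22[k], stringsAsFactors = FALSE)
  class(out) <- c("ibd_estimates", "data.frame")
  out
}

#' Prune related samples down to a target size
#'
#' Greedy heuristic: iteratively drops the sample with the largest
#' summed relatedness (`pi_hat`) to the remaining samples until
#' `target_n` remain. Ties break on the alphabetically smaller sample
#' id, so the result is deterministic. Greedy removal is a documented
#' stand-in for "exclude the highest-IBD animals"; it is not claimed
#' optimal.
#'
#' @param x A [genotype_matrix()].
#' @param target_n Number of samples to keep.
#' @param ibd Optional precomputed [ibd_estimates()] for `x`.
#' @return The pruned [genotype_matrix()].
#' @export
prune_related <- function(x, target_n, ibd = NULL) {
  if (target_n <= 0) stop("target_n must be positive")
  n <- n_samples(x)
  if (target_n > n) stop("target_n exceeds sample count")
  if (target_n == n) return(x)
  if (is.null(ibd)) ibd <- ibd_estimates(x)
  ids <- x$samples$id
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  P[cbind(match(ibd$sample_i, ids), match(ibd$sample_j, ids))] <- ibd$pi_hat
  P <- P + t(P)
  alive <- rep(TRUE, n)
  while (sum(alive) > target_n) {
    s <- rowSums(P[, alive, drop = FALSE]) - diag(P)
    s[!alive] <- -Inf
    top <- which(s == max(s[alive]))
    drop_i <- top[order(ids[top])][1L]
    alive[drop_i] <- FALSE
  }
  subset_genotypes(x, sample_idx = which(alive))
}
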