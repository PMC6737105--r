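# Vectorized EM for two-locus haplotype frequencies from unphased
# genotype count tables. Inputs are parallel vectors over locus pairs:
# T11/T10/T01/T00 are haplotype counts fixed by the unambiguous
# genotypes and DH the double-heterozygote count; returns r2.
em_r2_from_counts <- function(T11, T10, T01, T00, DH,
                              tol = 1e-12, max_iter = 1000L) {
  tot <- T11 + T10 + T01 + T00 + 2 * DH
  pc <- rep(0.5, length(tot))
  h11 <- h10 <- h01 <- h00 <- NULL
  for (it in seq_len(max_iter)) {
    h11 <- (T11 + pc * DH) / tot
    h00 <- (T00 + pc * DH) / tot
    h10 <- (T10 + (1 - pc) * DH) / tot
    h01 <- (T01 + (1 - pc) * DH) / tot
    coup <- h11 * h00
    rep_ <- h10 * h01
    pc_new <- ifelse(coup + rep_ > 0, coup / (coup + rep_), 0.5)
    pc_new[DH == 0] <- pc[DH == 0]    # no ambiguity: nothing to update
    delta <- max(abs(pc_new - pc), 0)
    pc <- pc_new
    if (delta < tol) break
  }
  pA <- h11 + h10
  pB <- h11 + h01
  D <- h11 - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  ifelse(denom > 0, D^2 / denom, NA_real_)
}

#' Pairwise within-chromosome linkage disequilibrium (r-squared)
#'
#' Computes r2 for every marker pair on a chromosome whose inter-marker
#' distance does not exceed `window_bp`. Two estimators are available:
#' `"em_haplotype"` estimates two-locus haplotype frequencies from the
#' unphased genotypes by EM (the classic cubic-likelihood approach) and
#' returns `D^2 / (pA qA pB qB)`; `"composite"` is the squared Pearson
#' correlation of dosage vectors, whose basis is the Burrows composite
#' disequilibrium. No r2 threshold is applied. Monomorphic loci cannot
#' enter a pair and are skipped with a reported count.
#'
#' @param x A QC'd [genotype_matrix()].
#' @param chromosome Chromosome id, or `NULL` for all chromosomes.
#' @param window_bp Maximum pair distance in bp (default 10 Mb).
#' @param estimator `"em_haplotype"` or `"composite"`.
#' @return Data frame of class `ld_pairs` with columns `chrom`, `id_i`,
#'   `id_j`, `pos_i`, `pos_j`, `distance_bp`, `r2`, `estimator`.
#' @export
pairwise_r2 <- function(x, chromosome = NULL, window_bp = 10e6,
                        estimator = c("em_haplotype", "composite")) {
  estimator <- match.arg(estimator)
  chroms <- unique(x$variants$chrom)
  if (is.null(chromosome)) {
    out <- lapply(chroms, function(cc)
      pairwise_r2(x, cc, window_bp, estimator))
    return(do.call(rbind, out))
  }
  if (!chromosome %in% chroms) stop("unknown chromosome: ", chromosome)
  idx <- which(x$variants$chrom == chromosome)
  if (length(idx) < 2L) stop("need >= 2 markers on ", chromosome)
  G <- x$calls[, idx, drop = FALSE]
  st <- per_marker_stats(G)
  poly <- !is.na(st$maf) & st$maf > 0
  n_mono <- sum(!poly)
  if (n_mono > 0)
    message(n_mono, " monomorphic locus/loci skipped on ", chromosome)
  G <- G[, poly, drop = FALSE]
  v <- x$variants[idx[poly], , drop = FALSE]
  m <- ncol(G)
  if (m < 2L) stop("fewer than 2 polymorphic markers on ", chromosome)

  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  dist <- abs(v$pos[ut[, 2L]] - v$pos[ut[, 1L]])
  sel <- dist <= window_bp
  ut <- ut[sel, , drop = FALSE]
  dist <- dist[sel]
  kk <- cbind(ut[, 1L], ut[, 2L])

  if (estimator == "composite") {
    cm <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
    r2 <- (cm^2)[kk]
  } else {
    I0 <- (!is.na(G) & G == 0L) + 0
    I1 <- (!is.na(G) & G == 1L) + 0
    I2 <- (!is.na(G) & G == 2L) + 0
    n22 <- crossprod(I2)[kk]; n21 <- crossprod(I2, I1)[kk]
    n20 <- crossprod(I2, I0)[kk]
    n12 <- crossprod(I1, I2)[kk]; n11 <- crossprod(I1)[kk]
    n10 <- crossprod(I1, I0)[kk]
    n02 <- crossprod(I0, I2)[kk]; n01 <- crossprod(I0, I1)[kk]
    n00 <- crossprod(I0)[kk]
    T11 <- 2 * n22 + n21 + n12
    T10 <- 2 * n20 + n21 + n10
    T01 <- 2 * n02 + n01 + n12
    T00 <- 2 * n00 + n01 + n10
    r2 <- em_r2_from_counts(T11, T10, T01, T00, n11)
  }
  keep <- !is.na(r2)
  out <- data.frame(chrom = chromosome,
                    id_i = v$id[ut[keep, 1L]], id_j = v$id[ut[keep, 2L]],
                    pos_i = v$pos[ut[keep, 1L]], pos_j = v$pos[ut[keep, 2L]],
                    distance_bp = dist[keep], r2 = r2[keep],
                    estimator = estimator, stringsAsFactors = FALSE)
  class(out) <- c("ld_pairs", "data.frame")
  out
}

#' Distance-binned LD decay curve
#'
#' Arithmetic mean r2 per half-open distance bin `[lo, hi)` of width
#' `bin_width` spanning 0 to `max_dist`, plus the overall mean and SD
#' across all pairs in range.
#'
#' @param pairs An `ld_pairs` data frame from [pairwise_r2()].
#' @param bin_width Bin width in bp (default 100 kb).
#' @param max_dist Maximum distance in bp (default 10 Mb).
#' @return List of class `ld_decay`: `bins` (data frame `lo`, `hi`,
#'   `mean_r2`, `n_pairs`; mean is `NA` for empty bins),
#'   `overall_mean`, `overall_sd`, `n_pairs`.
#' @export
bin_ld_decay <- function(pairs, bin_width = 100000, max_dist = 10e6) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (nrow(pairs) == 0L) stop("empty pair set")
  inr <- pairs$distance_bp < max_dist
  d <- pairs$distance_bp[inr]
  r2 <- pairs$r2[inr]
  n_bins <- ceiling(max_dist / bin_width)
  b <- pmin(floor(d / bin_width) + 1L, n_bins)
  mean_r2 <- rep(NA_real_, n_bins)
  agg_n <- tabulate(b, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(r2, b)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  mean_r2[agg_n > 0] <- sums[agg_n > 0] / agg_n[agg_n > 0]
  bins <- data.frame(lo = (seq_len(n_bins) - 1) * bin_width,
                     hi = seq_len(n_bins) * bin_width,
                     mean_r2 = mean_r2, n_pairs = agg_n)
  structure(list(bins = bins, overall_mean = mean(r2),
                 overall_sd = stats::sd(r2), n_pairs = length(r2)),
            class = "ld_decay")
}

#' Extract marker pairs in high LD
#'
#' Strict subset with `r2 > threshold` (so a threshold of 1 returns
#' nothing), sorted by chromosome then position.
#'
#' @param pairs An `ld_pairs` data frame.
#' @param threshold r2 cutoff in [0, 1] (default 0.80).
#' @return The filtered, sorted `ld_pairs` data frame.
#' @export
high_ld_pairs <- function(pairs, threshold = 0.80) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- pairs[pairs$r2 > threshold, , drop = FALSE]
  out <- out[order(out$chrom, out$pos_i, out$pos_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
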