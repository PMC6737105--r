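#' Quality-control thresholds
#'
#' Defaults follow common SNP-array practice in breeding populations:
#' markers dropped below 5% minor allele frequency, below an exact
#' Hardy-Weinberg p of 1e-6 or above 70% missingness; samples dropped
#' below a 95% genotype call rate.
#'
#' @param maf_min Minimum minor allele frequency (marker kept if
#'   `maf >= maf_min`).
#' @param hwe_p_min Minimum exact HWE p-value.
#' @param marker_missing_max Maximum marker missing fraction.
#' @param sample_callrate_min Minimum per-sample call rate.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 1e-6,
                          marker_missing_max = 0.70,
                          sample_callrate_min = 0.95) {
  th <- list(maf_min = maf_min, hwe_p_min = hwe_p_min,
             marker_missing_max = marker_missing_max,
             sample_callrate_min = sample_callrate_min)
  if (any(unlist(th) < 0) || any(unlist(th) > 1))
    stop("all thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Allele frequency of a single variant
#'
#' @param calls Vector of dosages in `{0, 1, 2, NA}` for one variant.
#' @return List with `p_alt` (alternate-allele frequency over called
#'   genotypes), `maf` and `n_called`.
#' @export
allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  n_called <- sum(ok)
  if (n_called == 0L) stop("all calls missing; allele frequency undefined")
  p_alt <- sum(calls[ok]) / (2 * n_called)
  list(p_alt = p_alt, maf = min(p_alt, 1 - p_alt), n_called = n_called)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the
#' heterozygote count follows the classic conditional distribution
#' P(h) = N! / (n_AA! h! n_aa!) * 2^h * n_A! n_a! / (2N)!; the p-value
#' sums the probabilities of all feasible heterozygote counts whose
#' probability does not exceed the observed one (plain exact test, no
#' mid-p).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("empty genotype table")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  if (nA == 0L || na == 0L) return(1)          # monomorphic: one table
  h_max <- min(nA, na)
  h <- seq.int(nA %% 2L, h_max, by = 2L)
  lp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

per_marker_stats <- function(calls) {
  n <- nrow(calls)
  n_called <- colSums(!is.na(calls))
  alt_sum <- colSums(calls, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt_sum / (2 * n_called), NA_real_)
  list(miss_frac = 1 - n_called / n,
       maf = pmin(p_alt, 1 - p_alt),
       n_het = colSums(calls == 1L, na.rm = TRUE),
       n_hom_alt = colSums(calls == 2L, na.rm = TRUE),
       n_called = n_called)
}

#' Apply marker and sample quality control
#'
#' Filters are applied in a fixed, documented order: (1) samples below
#' the call-rate threshold are dropped; then markers failing (2)
#' missingness, (3) minor allele frequency, (4) exact HWE are removed.
#' Each removed marker is attributed to the first criterion it fails in
#' that order, so the per-criterion counts partition the removed set.
#' Markers left with no called genotypes after sample removal land in
#' the `removed_other` bucket. The matrix is treated as a single
#' population; run per population for within-population QC.
#'
#' @param x A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (filtered matrix) and `report` (class
#'   `qc_report`: `removed_by_callrate`, `removed_by_maf`,
#'   `removed_by_hwe`, `removed_other`, `samples_removed`,
#'   `final_marker_count`).
#' @export
apply_qc <- function(x, thresholds = qc_thresholds()) {
  if (!inherits(thresholds, "qc_thresholds"))
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  if (n_variants(x) == 0L || n_samples(x) == 0L) stop("empty matrix")

  callrate <- rowMeans(!is.na(x$calls))
  bad_sample <- callrate < thresholds$sample_callrate_min
  if (any(bad_sample))
    x <- subset_genotypes(x, sample_idx = which(!bad_sample))

  st <- per_marker_stats(x$calls)
  other <- st$n_called == 0L
  miss <- !other & st$miss_frac > thresholds$marker_missing_max
  low_maf <- !other & !miss & st$maf < thresholds$maf_min
  hwe_p <- rep(1, n_variants(x))
  cand <- which(!other & !miss & !low_maf)
  for (j in cand) {
    n_aa <- st$n_hom_alt[j]
    n_het <- st$n_het[j]
    hwe_p[j] <- hwe_exact_test(st$n_called[j] - n_het - n_aa, n_het, n_aa)
  }
  bad_hwe <- !other & !miss & !low_maf & hwe_p < thresholds$hwe_p_min

  keep <- !(other | miss | low_maf | bad_hwe)
  report <- structure(list(removed_by_callrate = sum(miss),
                           removed_by_maf = sum(low_maf),
                           removed_by_hwe = sum(bad_hwe),
                           removed_other = sum(other),
                           samples_removed = sum(bad_sample),
                           final_marker_count = sum(keep)),
                      class = "qc_report")
  list(genotypes = subset_genotypes(x, variant_idx = which(keep)),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  markers removed by missingness:", x$removed_by_callrate, "\n")
  cat("  markers removed by MAF:        ", x$removed_by_maf, "\n")
  cat("  markers removed by HWE:        ", x$removed_by_hwe, "\n")
  cat("  markers removed (other):       ", x$removed_other, "\n")
  cat("  samples removed:               ", x$samples_removed, "\n")
  cat("  final marker count:            ", x$final_marker_count, "\n")
  invisible(x)
}

#' Minor-allele-frequency spectrum over stated bins
#'
#' @param x A QC'd [genotype_matrix()].
#' @param bins Two-column matrix or data frame of bin bounds
#'   `[lo, hi)`; the last bin is closed. Default: the five classic MAF
#'   classes 0.05-0.09, 0.10-0.19, 0.20-0.29, 0.30-0.39, 0.40-0.50.
#' @return Data frame with `lo`, `hi`, `n` and `proportion` (over SNPs
#'   falling in any bin; proportions sum to 1).
#' @export
maf_spectrum <- function(x, bins = cbind(lo = c(0.05, 0.10, 0.20, 0.30, 0.40),
                                         hi = c(0.10, 0.20, 0.30, 0.40, 0.50))) {
  bins <- as.data.frame(bins)
  names(bins) <- c("lo", "hi")
  bins <- bins[order(bins$lo), , drop = FALSE]
  if (any(bins$hi <= bins$lo) ||
      (nrow(bins) > 1 && any(bins$lo[-1] < bins$hi[-nrow(bins)] - 1e-12)))
    stop("bins must be non-overlapping with hi > lo")
  maf <- per_marker_stats(x$calls)$maf
  maf <- maf[!is.na(maf)]
  counts <- vapply(seq_len(nrow(bins)), function(b) {
    hi_ok <- if (b == nrow(bins)) maf <= bins$hi[b] + 1e-12
             else maf < bins$hi[b]
    sum(maf >= bins$lo[b] & hi_ok)
  }, numeric(1))
  tot <- sum(counts)
  if (tot == 0) stop("no SNPs fall in the stated bins")
  data.frame(lo = bins$lo, hi = bins$hi, n = counts,
             proportion = counts / tot)
}
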