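#' Construct a genotype matrix object
#'
#' The central container consumed by every analysis stage: a samples x
#' variants matrix of diploid alternate-allele dosages (0, 1, 2, or `NA`
#' for a missing call) together with a variant map and per-sample
#' population labels.
#'
#' @param calls Integer matrix, `n_samples` x `n_variants`, values in
#'   `{0, 1, 2, NA}`.
#' @param variants Data frame with columns `chrom` (character), `pos`
#'   (1-based bp, integer), `id` (unique variant id), `ref`, `alt`
#'   (single-base alleles).
#' @param samples Data frame with columns `id` (unique sample id) and
#'   `pop` (population label).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("id", "pop") %in% names(samples)))
    stop("samples must have columns: id, pop")
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but variants has ",
         nrow(variants), " rows")
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("calls must be in {0, 1, 2, NA}")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  # sort by chromosome (first-appearance order) then position
  chrom_lev <- unique(variants$chrom)
  ord <- order(match(variants$chrom, chrom_lev), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dup <- duplicated(variants[, c("chrom", "pos")])
  if (any(dup))
    stop("duplicate (chrom, pos) coordinates: ",
         paste(variants$id[dup][seq_len(min(3, sum(dup)))], collapse = ", "))
  dimnames(calls) <- list(samples$id, variants$id)
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", n_samples(x), " samples x ", n_variants(x),
      " variants on ", length(unique(x$variants$chrom)), " chromosome(s)\n",
      sep = "")
  pops <- table(x$samples$pop)
  cat("populations:", paste(names(pops), pops, sep = "=", collapse = ", "),
      "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing call rate: %.4f\n", miss))
  invisible(x)
}

#' Number of samples in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$calls)

#' Number of variants in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer count.
#' @export
n_variants <- function(x) ncol(x$calls)

#' Subset a genotype matrix by variant or sample index
#'
#' @param x A `genotype_matrix`.
#' @param variant_idx,sample_idx Integer or logical indices; `NULL`
#'   keeps everything.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, variant_idx = NULL, sample_idx = NULL) {
  if (is.null(variant_idx)) variant_idx <- seq_len(n_variants(x))
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(x))
  genotype_matrix(x$calls[sample_idx, variant_idx, drop = FALSE],
                  x$variants[variant_idx, , drop = FALSE],
                  x$samples[sample_idx, , drop = FALSE])
}

#' Split a genotype matrix by population label
#' @param x A `genotype_matrix`.
#' @return Named list of `genotype_matrix`, one per population label in
#'   first-appearance order.
#' @export
split_populations <- function(x) {
  labs <- unique(x$samples$pop)
  out <- lapply(labs, function(p)
    subset_genotypes(x, sample_idx = which(x$samples$pop == p)))
  names(out) <- labs
  out
}

#' Per-variant alternate-allele frequency for a whole matrix
#' @param x A `genotype_matrix`.
#' @return Numeric vector of alt-allele frequencies (NaN where all calls
#'   are missing).
#' @export
alt_freqs <- function(x) {
  colMeans(x$calls, na.rm = TRUE) / 2
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
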