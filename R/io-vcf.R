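#' Read a VCF file into a genotype matrix
#'
#' Loads biallelic SNP records from a VCF (v4.x) with GT genotypes.
#' Multiallelic and non-SNP records are skipped and their count
#' reported via a message. Half-calls and `./.` map to missing.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param pop Population label to attach to all samples (default
#'   `"POP1"`), or a named vector `sample id -> label`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, pop = "POP1") {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no sample columns")
  snp <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " multiallelic/non-SNP record(s) skipped")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  fix <- fix[snp, , drop = FALSE]
  gtm <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  gtm <- matrix(chartr("|", "/", gtm), nrow = nrow(gtm),
                dimnames = dimnames(gtm))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- matrix(unname(code[gtm]), nrow = nrow(gtm))  # others -> NA
  calls <- t(calls)                                     # samples x variants
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ids, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  sample_ids <- colnames(v@gt)[-1L]
  pops <- if (length(pop) == 1L && is.null(names(pop)))
    rep(pop, length(sample_ids)) else unname(pop[sample_ids])
  samples <- data.frame(id = sample_ids, pop = pops,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples)
}

#' Write a genotype matrix to a VCF v4.2 text file
#'
#' Emits GT-only records with contig header lines; missing calls are
#' written `./.`.
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  chroms <- unique(v$chrom)
  chrom_len <- vapply(chroms, function(cc)
    max(v$pos[v$chrom == cc]), numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popldne",
           sprintf("##contig=<ID=%s,length=%d>", chroms,
                   as.integer(chrom_len)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples$id), collapse = "\t"))
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_samples(x), ncol = n_variants(x))
  ok <- !is.na(x$calls)
  gt[ok] <- gtcode[x$calls[ok] + 1L]
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                sep = "\t")
  lines <- paste(body, apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
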