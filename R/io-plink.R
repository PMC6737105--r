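#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Allele pairs are converted to alternate-allele dosage. The PED format
#' does not say which allele is the alternate: by default the minor
#' allele in the file is taken as alt (the usual PLINK A1 convention,
#' alphabetical tie-break); pass `alt_alleles` to fix the mapping, e.g.
#' for exact round trips with a VCF of the same data. Allele code `0`
#' means missing.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param alt_alleles Optional character vector (one per MAP variant)
#'   naming the allele counted as alt.
#' @param pop Population label, or `"FID"` to use the PED family id
#'   column as the label.
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, alt_alleles = NULL,
                            pop = "FID") {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m)
    stop("PED has ", ncol(ped) - 6L, " allele columns but MAP lists ",
         m, " variants")
  n <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  ref <- alt <- character(m)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1, x2)
    obs <- obs[obs != "0"]
    lev <- sort(unique(obs))
    if (length(lev) > 2L)
      stop("variant ", map$id[j], " has more than two alleles")
    if (is.null(alt_alleles)) {
      cnt <- table(factor(obs, levels = lev))
      # minor allele as alt; alphabetical (later) tie-break
      altj <- if (length(lev) == 2L)
        lev[order(cnt, seq_along(lev))][1L] else NA_character_
    } else altj <- alt_alleles[j]
    refj <- setdiff(lev, altj)
    refj <- if (length(refj)) refj[1L] else "N"
    if (is.na(altj)) altj <- "N"
    alt[j] <- altj; ref[j] <- refj
    d <- (x1 == altj) + (x2 == altj)
    d[x1 == "0" | x2 == "0"] <- NA_integer_
    calls[, j] <- as.integer(d)
  }
  pops <- if (identical(pop, "FID")) ped[[1L]] else rep(pop, n)
  variants <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  samples <- data.frame(id = ped[[2L]], pop = pops,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples)
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' @param x A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_plink_text <- function(x, ped_path, map_path) {
  v <- x$variants
  utils::write.table(data.frame(v$chrom, v$id, 0, v$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- n_samples(x); m <- n_variants(x)
  al <- matrix("0", nrow = n, ncol = 2L * m)
  for (j in seq_len(m)) {
    g <- x$calls[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$alt[j], v$ref[j]))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$alt[j], v$ref[j]))
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  lead <- cbind(x$samples$pop, x$samples$id, "0", "0", "0", "-9")
  utils::write.table(cbind(lead, al), ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(list(ped = ped_path, map = map_path))
}

#' Intersect marker sets across populations
#'
#' Restricts each population's genotype matrix to the markers present
#' in all of them, matched by (chromosome, position, ref, alt), in a
#' common order. Mirrors the practice of analysing only markers shared
#' across independently QC'd populations.
#'
#' @param populations List of [genotype_matrix()] objects.
#' @return A list of class `population_set`: element `populations` (the
#'   subset matrices, identical variant maps) and `n_common` (retained
#'   marker count).
#' @export
intersect_markers <- function(populations) {
  stopifnot(length(populations) >= 1L)
  keys <- lapply(populations, function(p) variant_key(p$variants))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) stop("no markers shared across populations")
  out <- lapply(seq_along(populations), function(i) {
    idx <- match(common, keys[[i]])
    subset_genotypes(populations[[i]], variant_idx = idx)
  })
  names(out) <- names(populations)
  structure(list(populations = out, n_common = length(common)),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("population_set: ", length(x$populations), " population(s), ",
      x$n_common, " shared markers\n", sep = "")
  invisible(x)
}
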