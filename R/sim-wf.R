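#' Configuration for the forward Wright-Fisher simulator
#'
#' Defaults emulate a desk-scale version of a farmed-tilapia-like SNP
#' panel: a handful of chromosomes tens of Mb long with a marker every
#' 60-100 kb and a recombination rate of 1 cM/Mb.
#'
#' @param n_individuals Diploid individuals sampled from the final
#'   generation.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp (scalar or
#'   vector of length `n_chromosomes`).
#' @param marker_density Markers per Mb of chromosome.
#' @param recomb_rate Morgans per Mb (default 0.01, i.e. 1 cM/Mb).
#' @param ne_trajectory Data frame with columns `generation` and `N`
#'   giving diploid census-size breakpoints; the size holds from its
#'   breakpoint until the next one. Generation 1 is the first offspring
#'   generation after the founders.
#' @param n_generations Number of generations to simulate forward.
#' @param init_maf Either the string `"uniform"` with `init_maf_range`,
#'   giving founder minor-allele frequencies drawn site-independently
#'   from a uniform distribution, or a function `(m) -> freq vector`.
#' @param init_maf_range Range of the uniform founder MAF (default
#'   0.05-0.5).
#' @param monogamy Logical; lifetime monogamous parent pairs (default
#'   `TRUE`, matching a non-random-mating breeding design). `FALSE`
#'   draws two distinct parents at random per offspring.
#' @param missing_rate Per-call probability of masking a genotype as
#'   missing in the returned matrix (default 0).
#' @param pop_label Population label attached to the sampled
#'   individuals.
#' @param seed Integer seed; fixes the full output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 55,
                       n_chromosomes = 4,
                       chrom_length_bp = 40e6,
                       marker_density = 37,
                       recomb_rate = 0.01,
                       ne_trajectory = data.frame(generation = 1, N = 100),
                       n_generations = 200,
                       init_maf = "uniform",
                       init_maf_range = c(0.05, 0.5),
                       monogamy = TRUE,
                       missing_rate = 0,
                       pop_label = "SIM",
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = rep_len(as.numeric(chrom_length_bp),
                                        n_chromosomes),
              marker_density = marker_density,
              recomb_rate = recomb_rate,
              ne_trajectory = as.data.frame(ne_trajectory),
              n_generations = as.integer(n_generations),
              init_maf = init_maf,
              init_maf_range = init_maf_range,
              monogamy = isTRUE(monogamy),
              missing_rate = missing_rate,
              pop_label = pop_label,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals > 0, cfg$n_chromosomes > 0,
            all(cfg$chrom_length_bp > 0), cfg$marker_density > 0,
            cfg$recomb_rate >= 0, cfg$n_generations >= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  tr <- cfg$ne_trajectory
  if (!all(c("generation", "N") %in% names(tr)))
    stop("ne_trajectory needs columns generation and N")
  if (any(tr$N < 2))
    stop("ne_trajectory N values must be >= 2 (sexual reproduction ",
         "requires two parents)")
  invisible(cfg)
}

# census size per generation 1..n_generations as a step function of the
# breakpoints
expand_trajectory <- function(ne_trajectory, n_generations) {
  tr <- ne_trajectory[order(ne_trajectory$generation), , drop = FALSE]
  idx <- findInterval(seq_len(n_generations), tr$generation)
  idx[idx == 0L] <- 1L
  as.integer(tr$N[idx])
}

# one gamete with >= 1 crossover: mosaic of the two parental haplotypes
recombine_gamete <- function(h1, h2, pos, len_bp, ncross, start) {
  xp <- sort(stats::runif(ncross, 0, len_bp))
  seg <- (findInterval(pos, xp) + start) %% 2L
  out <- h1
  sel <- seg == 1L
  out[sel] <- h2[sel]
  out
}

#' Simulate a diploid population forward in time under Wright-Fisher
#' reproduction with recombination
#'
#' Discrete non-overlapping generations; each offspring draws two
#' parents (lifetime monogamous pairs by default), gametes are formed
#' with a Poisson number of crossovers per chromosome (mean = map length
#' in Morgans) at uniform positions. Founder haplotypes are drawn
#' site-independently from the configured minor-allele-frequency
#' distribution, so early-generation LD is below drift stationarity and
#' builds up over time; recovery analyses should therefore run on the
#' order of 2N generations of burn-in. The final generation is sampled
#' down to `n_individuals`. Monomorphic loci are retained (downstream QC
#' removes them).
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (a list with the realised `ne_trajectory`, the founder
#'   allele frequencies and the census sizes per generation).
#' @export
simulate_wf_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  len_bp <- config$chrom_length_bp
  m_per_chrom <- as.integer(round(config$marker_density * len_bp / 1e6))
  if (any(m_per_chrom < 1L))
    stop("configuration yields zero markers on a chromosome")
  pos_list <- lapply(seq_len(config$n_chromosomes), function(cc) {
    sort(sample.int(len_bp[cc], m_per_chrom[cc]))
  })
  len_morgans <- config$recomb_rate * len_bp / 1e6

  sizes <- expand_trajectory(config$ne_trajectory, config$n_generations)
  n0 <- sizes[1]
  if (config$n_individuals > sizes[length(sizes)])
    stop("n_individuals exceeds the final generation census size")

  # founder frequencies: minor allele = alt allele at founding
  freqs <- lapply(m_per_chrom, function(m) {
    if (is.function(config$init_maf)) config$init_maf(m)
    else stats::runif(m, config$init_maf_range[1], config$init_maf_range[2])
  })

  # haplotypes per chromosome: (2N) x m integer 0/1 matrices
  H <- lapply(seq_along(pos_list), function(cc) {
    m <- m_per_chrom[cc]
    matrix(stats::rbinom(2L * n0 * m, 1L, rep(freqs[[cc]], each = 2L * n0)),
           nrow = 2L * n0, ncol = m)
  })

  n_prev <- n0
  for (t in seq_len(config$n_generations)) {
    n_t <- sizes[t]
    if (n_prev < 2L) stop("population size 1 cannot reproduce sexually")
    if (config$monogamy) {
      perm <- sample.int(n_prev)
      n_pairs <- n_prev %/% 2L
      pair_a <- perm[seq_len(n_pairs)]
      pair_b <- perm[n_pairs + seq_len(n_pairs)]
      fam <- sample.int(n_pairs, n_t, replace = TRUE)
      par1 <- pair_a[fam]
      par2 <- pair_b[fam]
    } else {
      par1 <- sample.int(n_prev, n_t, replace = TRUE)
      par2 <- (par1 - 1L + sample.int(n_prev - 1L, n_t,
                                      replace = TRUE)) %% n_prev + 1L
    }
    parents <- c(par1, par2)          # gamete g comes from parents[g]
    n_gam <- 2L * n_t
    for (cc in seq_len(config$n_chromosomes)) {
      Hc <- H[[cc]]
      ncross <- stats::rpois(n_gam, len_morgans[cc])
      start <- sample.int(2L, n_gam, replace = TRUE) - 1L
      newH <- matrix(0L, nrow = n_gam, ncol = m_per_chrom[cc])
      plain <- ncross == 0L
      if (any(plain))
        newH[plain, ] <- Hc[2L * (parents[plain] - 1L) + 1L + start[plain], ,
                            drop = FALSE]
      for (g in which(!plain)) {
        h1 <- Hc[2L * parents[g] - 1L, ]
        h2 <- Hc[2L * parents[g], ]
        newH[g, ] <- recombine_gamete(h1, h2, pos_list[[cc]], len_bp[cc],
                                      ncross[g], start[g])
      }
      # interleave: offspring i -> rows 2i-1 (gamete i), 2i (gamete n_t+i)
      idx <- integer(n_gam)
      idx[seq(1L, n_gam, by = 2L)] <- seq_len(n_t)
      idx[seq(2L, n_gam, by = 2L)] <- n_t + seq_len(n_t)
      H[[cc]] <- newH[idx, , drop = FALSE]
    }
    n_prev <- n_t
  }

  keep <- sort(sample.int(n_prev, config$n_individuals))
  calls <- do.call(cbind, lapply(H, function(Hc) {
    Hc[2L * keep - 1L, , drop = FALSE] + Hc[2L * keep, , drop = FALSE]
  }))
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$missing_rate
    calls[mask] <- NA_integer_
  }

  chrom <- rep(sprintf("chr%d", seq_len(config$n_chromosomes)), m_per_chrom)
  pos <- unlist(pos_list, use.names = FALSE)
  variants <- data.frame(chrom = chrom, pos = pos,
                         id = sprintf("%s_%d", chrom, pos),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("%s_%03d", config$pop_label,
                                     seq_len(config$n_individuals)),
                        pop = config$pop_label, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, variants, samples)
  truth <- list(ne_trajectory = data.frame(generation =
                                             seq_len(config$n_generations),
                                           N = sizes),
                founder_freqs = unlist(freqs, use.names = FALSE),
                config = config)
  list(genotypes = gm, truth = truth)
}
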