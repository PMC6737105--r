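#' Configuration for the full analysis pipeline
#'
#' Every stage parameter is surfaced with the standard defaults: MAF
#' 0.05, HWE p 1e-6, call rate 0.95, 10-Mb LD window with 100-kb decay
#' bins, 30 x 50-kb Ne bins with alpha = 2, pcrit 0.05 with the
#' non-random (monogamy) mating model, and a genome length of 14.8
#' Morgans for the marker-requirement arithmetic.
#'
#' @param thresholds A [qc_thresholds()].
#' @param target_n Samples to keep per population after relatedness
#'   pruning (`NULL` keeps all).
#' @param ld_window_bp LD pair window (bp).
#' @param ld_bin_width Decay-curve bin width (bp).
#' @param ld_estimator r2 estimator for decay curves.
#' @param ne An [ne_settings()].
#' @param mating Mating model for contemporary Ne.
#' @param pcrit Allele-frequency screen for contemporary Ne.
#' @param regress_t_max Trajectory window for the regression Ne.
#' @param genome_morgans Genome length L in Morgans.
#' @param k_range Candidate K values for admixture (`NULL` skips the
#'   cross-validated scan; the largest K in the range is also fitted).
#' @param admixture_markers Marker subsample cap for the admixture EM
#'   stage (keeps the EM desk-scale; `Inf` uses all markers).
#' @param seed Integer seed fixing all stochastic stages.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = qc_thresholds(),
                            target_n = NULL,
                            ld_window_bp = 10e6,
                            ld_bin_width = 100000,
                            ld_estimator = "em_haplotype",
                            ne = ne_settings(),
                            mating = "monogamy",
                            pcrit = 0.05,
                            regress_t_max = 100,
                            genome_morgans = 14.8,
                            k_range = NULL,
                            admixture_markers = 2000L,
                            seed = 1L) {
  structure(list(thresholds = thresholds, target_n = target_n,
                 ld_window_bp = ld_window_bp, ld_bin_width = ld_bin_width,
                 ld_estimator = ld_estimator, ne = ne, mating = mating,
                 pcrit = pcrit, regress_t_max = regress_t_max,
                 genome_morgans = genome_morgans, k_range = k_range,
                 admixture_markers = admixture_markers,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full population-genomics analysis
#'
#' Orchestrates the stages in the canonical order: per-population QC,
#' marker intersection across populations, relatedness pruning to a
#' common sample size, population structure (heterozygosity, PCA,
#' pairwise Fst, ML admixture), within-chromosome LD with decay
#' curves, and effective population size (historical trajectory,
#' contemporary LD estimate, regression extrapolation, harmonic means,
#' Me and marker requirements). Writes per-stage TSVs when `out_dir`
#' is given. All stochastic stages are fixed by `config$seed`.
#'
#' @param populations Named list of single-population
#'   [genotype_matrix()] objects (or paths to VCF files).
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for stage TSVs.
#' @return A list bundle with per-stage results; see the elements
#'   `qc`, `pruned`, `het`, `pca`, `fst`, `admixture`, `ld`,
#'   `ne`, `summary_per_lg`.
#' @export
run_full_analysis <- function(populations, config = analysis_config(),
                              out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  populations <- lapply(populations, function(p)
    if (is.character(p)) read_vcf(p) else p)
  if (is.null(names(populations)))
    names(populations) <- vapply(populations, function(p)
      p$samples$pop[1L], character(1))
  set.seed(config$seed)

  # stage 1: QC per population
  qc_res <- lapply(populations, apply_qc, thresholds = config$thresholds)
  qc_tab <- do.call(rbind, lapply(names(qc_res), function(nm) {
    r <- qc_res[[nm]]$report
    data.frame(population = nm,
               removed_by_maf = r$removed_by_maf,
               removed_by_hwe = r$removed_by_hwe,
               removed_by_callrate = r$removed_by_callrate,
               removed_other = r$removed_other,
               samples_removed = r$samples_removed,
               final_markers = r$final_marker_count)
  }))
  write_tsv(qc_tab, out_dir, "qc_report.tsv")

  # stage 2: common markers
  pset <- intersect_markers(lapply(qc_res, `[[`, "genotypes"))
  pops <- pset$populations

  # stage 3: relatedness pruning to a common size
  if (!is.null(config$target_n)) {
    pops <- lapply(pops, function(p)
      if (n_samples(p) > config$target_n)
        prune_related(p, config$target_n) else p)
  }
  combined <- genotype_matrix(
    do.call(rbind, lapply(pops, `[[`, "calls")),
    pops[[1L]]$variants,
    do.call(rbind, lapply(pops, `[[`, "samples")))

  # stage 4: population structure
  het <- lapply(pops, heterozygosity)
  het_tab <- data.frame(population = names(het),
                        Ho = vapply(het, `[[`, 0, "Ho"),
                        He = vapply(het, `[[`, 0, "He"))
  write_tsv(het_tab, out_dir, "heterozygosity.tsv")
  pca <- snp_pca(combined, k = min(5L, n_samples(combined) - 1L,
                                   n_variants(combined) - 1L))
  write_tsv(cbind(data.frame(sample = rownames(pca$coordinates),
                             pop = combined$samples$pop),
                  as.data.frame(pca$coordinates)),
            out_dir, "pca_scores.tsv")
  write_tsv(data.frame(component = seq_along(pca$explained_fraction),
                       explained_fraction = pca$explained_fraction),
            out_dir, "pca_explained.tsv")
  pairs_idx <- utils::combn(names(pops), 2, simplify = FALSE)
  fst <- lapply(pairs_idx, function(pr)
    weir_cockerham_fst(pops[pr]))
  names(fst) <- vapply(pairs_idx, paste, "", collapse = "_vs_")
  fst_tab <- data.frame(pair = names(fst),
                        fst_ratio_of_sums = vapply(fst, `[[`, 0,
                                                   "mean_theta"),
                        fst_mean = vapply(fst, `[[`, 0, "mean_of_ratios"),
                        fst_sd = vapply(fst, `[[`, 0, "sd_theta"))
  write_tsv(fst_tab, out_dir, "fst.tsv")

  adm <- NULL
  if (!is.null(config$k_range)) {
    xadm <- combined
    if (n_variants(xadm) > config$admixture_markers) {
      sub <- sort(sample.int(n_variants(xadm), config$admixture_markers))
      xadm <- subset_genotypes(xadm, variant_idx = sub)
    }
    cv <- if (length(config$k_range) > 1L)
      select_k(xadm, config$k_range, folds = 3L, seed = config$seed)
    else NULL
    k_best <- if (is.null(cv)) config$k_range
              else cv$K[which.min(cv$cv_error)]
    fit <- admixture_em(xadm, k_best, seed = config$seed)
    adm <- list(cv = cv, k_best = k_best, fit = fit)
    write_tsv(cbind(data.frame(sample = combined$samples$id,
                               pop = combined$samples$pop),
                    as.data.frame(fit$Q)),
              out_dir, "admixture_Q.tsv")
    if (!is.null(cv)) write_tsv(cv, out_dir, "admixture_cv.tsv")
  }

  # stage 5: LD
  ld <- lapply(pops, function(p) {
    prs <- pairwise_r2(p, window_bp = config$ld_window_bp,
                       estimator = config$ld_estimator)
    list(pairs = prs,
         decay = bin_ld_decay(prs, bin_width = config$ld_bin_width,
                              max_dist = config$ld_window_bp),
         high = high_ld_pairs(prs))
  })
  for (nm in names(ld))
    write_tsv(ld[[nm]]$decay$bins, out_dir,
              paste0("ld_decay_", nm, ".tsv"))

  # stage 6: effective population size
  ne <- lapply(names(pops), function(nm) {
    p <- pops[[nm]]
    traj <- historical_ne(ld[[nm]]$pairs, S = n_samples(p),
                          settings = config$ne)
    ctmp <- contemporary_ne_ld(p, mating = config$mating,
                               pcrit = config$pcrit)
    reg <- tryCatch(regress_contemporary(traj, config$regress_t_max),
                    error = function(e) NA_real_)
    req <- if (is.finite(ctmp$ne))
      marker_requirements(ctmp$ne, config$genome_morgans) else NULL
    list(trajectory = traj, contemporary = ctmp, regression = reg,
         requirements = req)
  })
  names(ne) <- names(pops)
  ne_tab <- data.frame(population = names(ne),
                       contemporary_ne = vapply(ne, function(z)
                         z$contemporary$ne, numeric(1)),
                       regression_ne = vapply(ne, function(z)
                         z$regression, numeric(1)),
                       harmonic_ne = vapply(ne, function(z)
                         z$trajectory$harmonic_overall, numeric(1)))
  write_tsv(ne_tab, out_dir, "ne_summary.tsv")
  for (nm in names(ne))
    write_tsv(ne[[nm]]$trajectory$points, out_dir,
              paste0("ne_trajectory_", nm, ".tsv"))

  # Table-2-style per-chromosome summary
  summary_per_lg <- do.call(rbind, lapply(names(pops), function(nm) {
    p <- pops[[nm]]
    prs <- ld[[nm]]$pairs
    hm <- ne[[nm]]$trajectory$harmonic_per_chromosome
    do.call(rbind, lapply(unique(p$variants$chrom), function(cc) {
      on_c <- prs$chrom == cc
      data.frame(population = nm, chrom = cc,
                 n_snps = sum(p$variants$chrom == cc),
                 size_mb = diff(range(p$variants$pos[
                   p$variants$chrom == cc])) / 1e6,
                 mean_r2 = mean(prs$r2[on_c]),
                 sd_r2 = stats::sd(prs$r2[on_c]),
                 harmonic_ne = unname(hm[cc]))
    }))
  }))
  write_tsv(summary_per_lg, out_dir, "summary_per_lg.tsv")

  list(qc = list(reports = lapply(qc_res, `[[`, "report"), table = qc_tab),
       n_common_markers = pset$n_common,
       pruned = pops, combined = combined,
       het = het_tab, pca = pca, fst = fst, fst_table = fst_tab,
       admixture = adm, ld = ld, ne = ne, ne_table = ne_tab,
       summary_per_lg = summary_per_lg, config = config)
}
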