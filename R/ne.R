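#' Sample-size adjustment of LD
#'
#' Subtracts the expected spurious correlation from finite sampling:
#' `r2_adj = r2 - 1/S` (the literal form used with chromosome-segment
#' LD; the contemporary-Ne routine uses its own published correction).
#' Negative adjusted values are passed through so callers can flag the
#' bin as unusable.
#'
#' @param r2 Raw r2 value(s).
#' @param S Sample size (diploid individuals), >= 2.
#' @return Adjusted r2.
#' @export
adjust_r2 <- function(r2, S) {
  if (S < 2) stop("sample size S must be >= 2")
  r2 - 1 / S
}

#' Recombination-distance mapping functions
#'
#' Converts genetic map distance d (Morgans) to recombination fraction
#' c: `"identity"` uses c = d, `"haldane"` uses
#' c = (1 - exp(-2 d)) / 2, `"sved_feldman"` uses c = d / (1 + 2 d).
#'
#' @param name Mapping name.
#' @return A function of distance in Morgans.
#' @export
mapping_function <- function(name = c("identity", "haldane",
                                      "sved_feldman")) {
  name <- match.arg(name)
  switch(name,
         identity = function(d) d,
         haldane = function(d) (1 - exp(-2 * d)) / 2,
         sved_feldman = function(d) d / (1 + 2 * d))
}

#' Invert the Sved equation for effective population size
#'
#' The expected adjusted LD at recombination fraction c is
#' `E[r2_adj] = 1 / (alpha + 4 f(c) Ne)`; solving for Ne gives
#' `Ne = (1 / r2_adj - alpha) / (4 f(c))`. With `alpha = 2` the
#' relation accounts for mutation. Bins whose adjusted LD is
#' non-positive, or that imply non-positive Ne (`1 / r2_adj <= alpha`),
#' are rejected and return `NA`.
#'
#' @param mean_r2_adj Adjusted mean r2 per bin (vectorized).
#' @param c_t Recombination fraction(s), in (0, 0.5].
#' @param alpha Mutation adjustment (default 2).
#' @param f Mapping applied to `c_t` inside the equation (default
#'   identity).
#' @return Ne estimate(s); `NA` for rejected bins.
#' @export
sved_ne <- function(mean_r2_adj, c_t, alpha = 2, f = identity) {
  stopifnot(all(c_t > 0), all(c_t <= 0.5 + 1e-12))
  ne <- (1 / mean_r2_adj - alpha) / (4 * f(c_t))
  ne[!is.finite(ne) | mean_r2_adj <= 0 | ne <= 0] <- NA_real_
  ne
}

#' Harmonic mean of effective-size values
#'
#' @param values Positive Ne values (per chromosome or per generation).
#' @return `k / sum(1 / values)`.
#' @export
harmonic_mean_ne <- function(values) {
  if (length(values) == 0L) stop("no values")
  if (any(values <= 0)) stop("harmonic mean requires positive values")
  length(values) / sum(1 / values)
}

#' Settings for historical-Ne estimation from binned LD
#'
#' Defaults mirror common chromosome-segment practice: 30 distance bins
#' of 50 kb, mutation adjustment alpha = 2, 1 cM/Mb (1e-8 Morgans/bp),
#' identity mapping, and the `r2 - 1/S` sample-size adjustment; bins
#' with fewer than `min_pairs` pairs are dropped.
#'
#' @param n_bins,bin_size,alpha,morgans_per_bp,mapping,min_pairs See
#'   description.
#' @return A list of class `ne_settings`.
#' @export
ne_settings <- function(n_bins = 30L, bin_size = 50000, alpha = 2,
                        morgans_per_bp = 1e-8, mapping = "identity",
                        min_pairs = 50L) {
  structure(list(n_bins = as.integer(n_bins), bin_size = bin_size,
                 alpha = alpha, morgans_per_bp = morgans_per_bp,
                 mapping = mapping, min_pairs = as.integer(min_pairs)),
            class = "ne_settings")
}

#' Historical effective population size from binned LD
#'
#' LD at recombination fraction c reflects effective size roughly
#' t = 1 / (2 c) generations ago, so distance bins probe a trajectory:
#' pairs are grouped into `n_bins` bins of `bin_size` bp per
#' chromosome; each bin's mean r2 is sample-size adjusted
#' (`r2 - 1/S`), its midpoint distance converted to Morgans
#' (`morgans_per_bp`) and mapped to a recombination fraction, and the
#' Sved relation inverted for Ne. Smaller distances probe older
#' generations. Per-chromosome trajectories are combined per generation
#' by harmonic mean; per-chromosome and overall harmonic-mean Ne are
#' also returned.
#'
#' @param pairs An `ld_pairs` data frame (any number of chromosomes).
#' @param S Diploid sample size used to genotype the pairs.
#' @param settings An [ne_settings()].
#' @return List of class `ne_trajectory`: `points` (data frame `t`,
#'   `c`, `mean_r2_adj`, `Ne`, `n_pairs`, ordered by `t`),
#'   `per_chromosome` (per-LG points), `harmonic_per_chromosome`,
#'   `harmonic_overall`, `settings`, `S`.
#' @export
historical_ne <- function(pairs, S, settings = ne_settings()) {
  if (S < 2) stop("sample size S must be >= 2")
  fmap <- mapping_function(settings$mapping)
  max_d <- settings$n_bins * settings$bin_size
  per_chrom <- lapply(split(pairs, pairs$chrom), function(pp) {
    d <- pp$distance_bp
    sel <- d < max_d
    if (!any(sel)) return(NULL)
    b <- floor(d[sel] / settings$bin_size) + 1L
    n_b <- tabulate(b, nbins = settings$n_bins)
    sums <- numeric(settings$n_bins)
    rs <- rowsum(pp$r2[sel], b)
    sums[as.integer(rownames(rs))] <- rs[, 1L]
    mid <- (seq_len(settings$n_bins) - 0.5) * settings$bin_size
    cc <- fmap(mid * settings$morgans_per_bp)
    mean_r2 <- ifelse(n_b > 0, sums / pmax(n_b, 1L), NA_real_)
    r2a <- adjust_r2(mean_r2, S)
    ne <- sved_ne(r2a, cc, alpha = settings$alpha)
    df <- data.frame(t = as.integer(round(1 / (2 * cc))), c = cc,
                     mean_r2_adj = r2a, Ne = ne, n_pairs = n_b)
    ok <- n_b >= settings$min_pairs & !is.na(ne)
    dropped <- sum(n_b > 0 & !ok)
    if (dropped > 0)
      message(dropped, " bin(s) dropped on ", pp$chrom[1L],
              " (sparse pairs or non-positive adjusted LD/Ne)")
    df[ok, , drop = FALSE]
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  per_chrom <- per_chrom[vapply(per_chrom, nrow, 0L) > 0L]
  if (length(per_chrom) == 0L) stop("no usable distance bins")
  all_pts <- do.call(rbind, Map(function(df, nm)
    cbind(chrom = nm, df, stringsAsFactors = FALSE),
    per_chrom, names(per_chrom)))
  comb <- do.call(rbind, lapply(split(all_pts, all_pts$t), function(g) {
    data.frame(t = g$t[1L], c = g$c[1L],
               mean_r2_adj = sum(g$mean_r2_adj * g$n_pairs) / sum(g$n_pairs),
               Ne = harmonic_mean_ne(g$Ne), n_pairs = sum(g$n_pairs))
  }))
  comb <- comb[order(comb$t), , drop = FALSE]
  rownames(comb) <- NULL
  structure(list(points = comb, per_chromosome = per_chrom,
                 harmonic_per_chromosome =
                   vapply(per_chrom, function(df)
                     harmonic_mean_ne(df$Ne), numeric(1)),
                 harmonic_overall = harmonic_mean_ne(comb$Ne),
                 settings = settings, S = S),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("historical Ne trajectory: ", nrow(x$points), " generations from t=",
      min(x$points$t), " to t=", max(x$points$t), "\n", sep = "")
  cat(sprintf("harmonic mean Ne: %.1f\n", x$harmonic_overall))
  invisible(x)
}

waples_sampling_expectation <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

waples_ne_from_r2prime <- function(r2p, S, mating) {
  co <- if (S >= 30) {
    if (mating == "random") c(a = 1 / 3, b = 2.76)
    else c(a = 2 / 3, b = 7.2)
  } else {
    if (mating == "random") c(a = 0.308, b = 2.08)
    else c(a = 0.618, b = 5.24)
  }
  disc <- co["a"]^2 - co["b"] * r2p
  if (r2p <= 0 || disc < 0) return(Inf)
  unname((co["a"] + sqrt(disc)) / (2 * r2p))
}

#' Contemporary effective population size by the bias-corrected LD
#' method
#'
#' Burrows composite-disequilibrium r2 (the squared Pearson correlation
#' of dosage vectors, whose basis is the composite measure) over locus
#' pairs, after excluding loci whose minor allele frequency falls below
#' `pcrit`. The mean r2 is reduced by the published second-order
#' sampling expectation and converted to Ne with the bias-corrected
#' constants of the LD method; the `"monogamy"` variant implements the
#' non-random (lifetime monogamous) mating model. Pairs of loci on
#' different chromosomes are used when more than one chromosome is
#' present (the method's constants assume unlinked loci); a
#' single-chromosome panel falls back to all pairs. The confidence
#' interval is a delete-one-chromosome jackknife.
#'
#' @param x A QC'd single-population [genotype_matrix()] with >= 10
#'   samples.
#' @param mating `"monogamy"` (default) or `"random"`.
#' @param pcrit Minor-allele-frequency screen (default 0.05).
#' @return List of class `contemporary_ne`: `ne`, `ci` (jackknife 95%,
#'   `NA` with < 3 chromosomes), `mean_r2`, `r2_prime`, `S`, `n_pairs`,
#'   `n_loci`, `mating`, `pcrit`.
#' @export
contemporary_ne_ld <- function(x, mating = c("monogamy", "random"),
                               pcrit = 0.05) {
  mating <- match.arg(mating)
  if (n_samples(x) < 10L) stop("need >= 10 samples")
  st <- per_marker_stats(x$calls)
  keep <- !is.na(st$maf) & st$maf >= pcrit & st$maf > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 loci pass the pcrit = ", pcrit, " screen")
  G <- x$calls[, keep, drop = FALSE]
  chrom <- x$variants$chrom[keep]
  S <- mean(st$n_called[keep])
  cm <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
  chroms <- unique(chrom)
  inter <- length(chroms) > 1L
  pair_mask <- upper.tri(cm) &
    (if (inter) outer(chrom, chrom, "!=") else TRUE)
  est_one <- function(mask) {
    r2s <- cm[mask]
    r2s <- r2s[!is.na(r2s)]
    r2p <- mean(r2s) - waples_sampling_expectation(S)
    list(ne = waples_ne_from_r2prime(r2p, S, mating),
         mean_r2 = mean(r2s), r2_prime = r2p, n_pairs = length(r2s))
  }
  full <- est_one(pair_mask)
  ci <- c(NA_real_, NA_real_)
  if (length(chroms) >= 3L) {
    jk <- vapply(chroms, function(cc) {
      keep_c <- chrom != cc
      est_one(pair_mask & outer(keep_c, keep_c, "&"))$ne
    }, numeric(1))
    if (all(is.finite(jk))) {
      k <- length(jk)
      jv <- (k - 1) / k * sum((jk - mean(jk))^2)
      ci <- full$ne + c(-1.96, 1.96) * sqrt(jv)
    }
  }
  structure(list(ne = full$ne, ci = ci, mean_r2 = full$mean_r2,
                 r2_prime = full$r2_prime, S = S,
                 n_pairs = full$n_pairs, n_loci = sum(keep),
                 mating = mating, pcrit = pcrit),
            class = "contemporary_ne")
}

#' @export
print.contemporary_ne <- function(x, ...) {
  cat(sprintf("contemporary Ne (LD method, %s mating, pcrit %.2f): %.1f\n",
              x$mating, x$pcrit, x$ne))
  if (all(is.finite(x$ci)))
    cat(sprintf("  jackknife 95%% CI: [%.1f, %.1f]\n", x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Contemporary Ne by linear extrapolation of the historical trajectory
#'
#' Ordinary least squares of Ne on t over the most recent trajectory
#' points, predicted at t = 1.
#'
#' @param trajectory An [historical_ne()] result, or a data frame with
#'   columns `t` and `Ne`.
#' @param t_max Use points with `t <= t_max` (default 100).
#' @return The predicted contemporary Ne.
#' @export
regress_contemporary <- function(trajectory, t_max = 100) {
  pts <- if (inherits(trajectory, "ne_trajectory")) trajectory$points
         else as.data.frame(trajectory)
  pts <- pts[pts$t <= t_max, , drop = FALSE]
  if (nrow(pts) < 2L) stop("need >= 2 trajectory points with t <= ", t_max)
  fit <- stats::lm(Ne ~ t, data = pts)
  pred <- unname(stats::predict(fit, newdata = data.frame(t = 1)))
  if (pred <= 0) stop("regression predicts non-positive contemporary Ne")
  pred
}

#' Effective number of chromosome segments
#'
#' `Me = 4 Ne L` for genome length L in Morgans; this is the number of
#' independently segregating genome chunks that governs how many
#' markers genomic prediction needs.
#'
#' @param Ne Effective population size (> 0).
#' @param L Genome length in Morgans (> 0).
#' @return List with `Me` (raw) and `Me_rounded` (nearest hundred, the
#'   reporting convention).
#' @export
effective_segments <- function(Ne, L) {
  if (any(Ne <= 0) || any(L <= 0)) stop("Ne and L must be positive")
  me <- 4 * Ne * L
  list(Me = me, Me_rounded = round(me / 100) * 100)
}

#' Marker and individual requirements for genomic prediction
#'
#' For unrelated individuals, accuracies of genomic prediction in the
#' 0.88-0.93 range call for about `2 Ne L` individuals and `10 Ne L`
#' markers.
#'
#' @param Ne Effective population size (> 0).
#' @param L Genome length in Morgans (> 0).
#' @return List with raw and nearest-hundred-rounded `markers_10NeL`
#'   and `individuals_2NeL`, plus `Me` from [effective_segments()].
#' @export
marker_requirements <- function(Ne, L) {
  if (any(Ne <= 0) || any(L <= 0)) stop("Ne and L must be positive")
  mk <- 10 * Ne * L
  ind <- 2 * Ne * L
  me <- effective_segments(Ne, L)
  list(markers_10NeL = mk,
       markers_10NeL_rounded = round(mk / 100) * 100,
       individuals_2NeL = ind,
       individuals_2NeL_rounded = round(ind / 100) * 100,
       Me = me$Me, Me_rounded = me$Me_rounded)
}
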