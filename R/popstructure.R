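#' Principal component analysis of standardized genotypes
#'
#' Genotypes are centered by twice the sample allele frequency and
#' scaled by `sqrt(2 p (1 - p))` per locus (the usual SNP-PCA
#' standardization); monomorphic loci are dropped and missing calls are
#' mean-imputed (zero after centering) for the projection only. The
#' sample-space Gram matrix of the standardized genotypes is
#' eigendecomposed; its non-zero eigenvalues equal those of the
#' locus-space covariance, so explained fractions are eigenvalue /
#' trace.
#'
#' @param x A QC'd [genotype_matrix()].
#' @param k Number of components, `k < min(n_samples, n_variants)`.
#' @return List of class `pca_result`: `coordinates` (n x k scores),
#'   `explained_fraction` (length k), `eigenvalues`, and
#'   `missing_rate` (mean-imputation becomes consequential above ~1%;
#'   interpret the leading components with care then).
#' @export
snp_pca <- function(x, k = 2L) {
  n <- n_samples(x); m <- n_variants(x)
  if (k >= min(n, m)) stop("k must be < min(n_samples, n_variants)")
  G <- x$calls
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  mm <- ncol(Z)
  Gram <- tcrossprod(Z) / mm
  ev <- eigen(Gram, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  tr <- sum(diag(Gram))
  coords <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)] * mm), k, k)
  rownames(coords) <- x$samples$id
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 explained_fraction = vals[seq_len(k)] / tr,
                 eigenvalues = vals,
                 missing_rate = mean(is.na(G))),
            class = "pca_result")
}

#' Observed and expected heterozygosity
#'
#' @param x A QC'd [genotype_matrix()].
#' @param unbiased Apply the small-sample correction
#'   `2n / (2n - 1)` to expected heterozygosity (default `FALSE`).
#' @return List of class `het_result` with `Ho` (mean over loci of the
#'   heterozygous-call fraction) and `He` (mean over loci of
#'   `2 p (1 - p)`).
#' @export
heterozygosity <- function(x, unbiased = FALSE) {
  st <- per_marker_stats(x$calls)
  ok <- st$n_called > 0L
  if (!any(ok & st$maf > 0)) stop("no polymorphic loci")
  p <- (st$n_het + 2 * st$n_hom_alt)[ok] / (2 * st$n_called[ok])
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * 2 * st$n_called[ok] / (2 * st$n_called[ok] - 1)
  structure(list(Ho = mean(st$n_het[ok] / st$n_called[ok]),
                 He = mean(he)),
            class = "het_result")
}

wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nC <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nC * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Weir-Cockerham Fst between two populations
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) from the
#' two-level weighted analysis of variance accommodating unequal sample
#' sizes; theta per locus is a / (a + b + c). The headline estimate is
#' the ratio of sums across loci; the mean and SD of per-locus theta
#' are reported alongside because per-locus dispersion is substantial
#' on SNP data.
#'
#' @param x Either a [genotype_matrix()] carrying exactly two
#'   population labels, or a list of two single-population matrices
#'   sharing a variant map.
#' @return List of class `fst_result`: `per_locus` data frame (id, a,
#'   b, c, theta), `mean_theta` (ratio of sums), `mean_of_ratios`,
#'   `sd_theta`, `n_loci_used`.
#' @export
weir_cockerham_fst <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    pops <- split_populations(x)
  } else pops <- x
  if (length(pops) != 2L) stop("exactly two populations required")
  g1 <- pops[[1L]]; g2 <- pops[[2L]]
  if (!identical(variant_key(g1$variants), variant_key(g2$variants)))
    stop("populations must share an identical variant map")
  if (n_samples(g1) < 2L || n_samples(g2) < 2L)
    stop("each population needs >= 2 samples")
  s1 <- per_marker_stats(g1$calls); s2 <- per_marker_stats(g2$calls)
  if (all(s1$n_called == 0L) || all(s2$n_called == 0L))
    stop("a population has no called genotypes")
  ok <- s1$n_called >= 2L & s2$n_called >= 2L
  p1 <- (s1$n_het + 2 * s1$n_hom_alt)[ok] / (2 * s1$n_called[ok])
  p2 <- (s2$n_het + 2 * s2$n_hom_alt)[ok] / (2 * s2$n_called[ok])
  comp <- wc_components(s1$n_called[ok], s2$n_called[ok], p1, p2,
                        s1$n_het[ok] / s1$n_called[ok],
                        s2$n_het[ok] / s2$n_called[ok])
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(denom != 0, comp$a / denom, NA_real_)
  per_locus <- data.frame(id = g1$variants$id[ok], a = comp$a, b = comp$b,
                          c = comp$c, theta = theta,
                          stringsAsFactors = FALSE)
  used <- !is.na(theta)
  structure(list(per_locus = per_locus,
                 mean_theta = sum(comp$a[used]) / sum(denom[used]),
                 mean_of_ratios = mean(theta[used]),
                 sd_theta = stats::sd(theta[used]),
                 n_loci_used = sum(used)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham Fst: %.4f (ratio of sums over %d loci)\n",
              x$mean_theta, x$n_loci_used))
  cat(sprintf("  per-locus mean +/- SD: %.4f +/- %.4f\n",
              x$mean_of_ratios, x$sd_theta))
  invisible(x)
}

binom_loglik <- function(G, mu) {
  ok <- !is.na(G)
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  sum(stats::dbinom(G[ok], 2L, mu[ok], log = TRUE))
}

#' Maximum-likelihood admixture proportions by EM
#'
#' Fits the classic admixture likelihood: dosage `g_ij` is
#' Binomial(2, sum_k Q_ik P_kj) with ancestry fractions `Q` on the
#' simplex and ancestral allele frequencies `P`. Fitted by EM from a
#' seeded random start; the log-likelihood is non-decreasing by
#' construction and iteration stops when its change drops below `tol`.
#' This is the maximum-likelihood analogue of Bayesian MCMC clustering:
#' same likelihood family, deterministic given the seed; results are
#' labelled "admixture (ML)" accordingly.
#'
#' @param x A QC'd [genotype_matrix()].
#' @param K Number of ancestral components, `1 <= K <= n_samples`.
#' @param seed Integer seed for the random start.
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return List of class `admixture_fit`: `Q` (n x K), `P` (K x m),
#'   `loglik_trace`, `converged`, `K`.
#' @export
admixture_em <- function(x, K, seed = 1L, tol = 1e-6, max_iter = 1000L) {
  n <- n_samples(x); m <- n_variants(x)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of samples")
  G <- x$calls
  ok <- !is.na(G)
  Gz <- G; Gz[!ok] <- 0L
  Rz <- 2L - G; Rz[!ok] <- 0L
  m_called2 <- 2 * rowSums(ok)

  set.seed(as.integer(seed))
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  pj <- colSums(Gz) / pmax(2 * colSums(ok), 1)
  P <- matrix(pmin(pmax(rep(pj, each = K) +
                          stats::runif(K * m, -0.1, 0.1), 0.01), 0.99),
              K, m)
  eps <- 1e-12
  trace <- numeric(0)
  ll_old <- -Inf
  # E-step responsibilities enter only through the row/column reductions
  # of the expected allele-copy matrices, so the whole update collapses
  # to a handful of matrix products:
  #   expected alt copies from component k: (Q_k outer P_k) * G / mu
  #   rowSums -> Q * ((G/mu) P^T), colSums -> P_k * crossprod(G/mu, Q)_k
  ll_const <- sum(lchoose(2L, G[ok]))
  for (it in seq_len(max_iter)) {
    MU <- Q %*% P
    MU[MU < eps] <- eps; MU[MU > 1 - eps] <- 1 - eps
    ll <- sum(Gz * log(MU) + Rz * log(1 - MU)) + ll_const
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    Ralt <- Gz / MU
    Rref <- Rz / (1 - MU)
    RA <- Q * (Ralt %*% t(P))        # n x K: per-sample alt copies by k
    RB <- Q * (Rref %*% t(1 - P))    # n x K: per-sample ref copies by k
    Qnew <- (RA + RB) / m_called2
    CA <- t(crossprod(Ralt, Q)) * P            # K x m alt copies by k
    CB <- t(crossprod(Rref, Q)) * (1 - P)      # K x m ref copies by k
    Pnew <- CA / pmax(CA + CB, eps)
    Q <- Qnew / rowSums(Qnew)
    P <- Pnew
    P[P < eps] <- eps; P[P > 1 - eps] <- 1 - eps
  }
  structure(list(Q = Q, P = P, loglik_trace = trace,
                 converged = it < max_iter, K = K),
            class = "admixture_fit")
}

#' Align an estimated Q matrix to a reference under label permutation
#'
#' Ancestry components are identifiable only up to label permutation;
#' this searches all permutations (K <= 8) for the one minimizing the
#' mean absolute error against the reference.
#'
#' @param Q Estimated n x K matrix.
#' @param Q_ref Reference n x K matrix.
#' @return List with `Q` (permuted estimate), `perm`, `mae`.
#' @export
align_q_matrices <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, K <= 8)
  perms <- permutations_of(K)
  maes <- vapply(perms, function(pp) mean(abs(Q[, pp] - Q_ref)), numeric(1))
  best <- which.min(maes)
  list(Q = Q[, perms[[best]], drop = FALSE], perm = perms[[best]],
       mae = maes[best])
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- list()
  for (s in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1L]] <- append(s, K, after = pos - 1L)
  }
  out
}

#' Choose K by masked-genotype cross-validation
#'
#' For each candidate K and fold, a random fraction of the non-missing
#' calls is masked, the admixture model is fitted on the rest, and the
#' masked dosages are predicted as `2 Q P`; the mean squared dosage
#' error over masked calls, averaged over folds, scores each K.
#'
#' @param x A QC'd [genotype_matrix()].
#' @param k_range Candidate values of K.
#' @param folds Number of masking folds (>= 2).
#' @param seed Integer seed.
#' @param mask_fraction Fraction of non-missing calls masked per fold
#'   (default 0.05; must be > 0).
#' @param ... Passed to [admixture_em()].
#' @return Data frame with `K` and `cv_error`.
#' @export
select_k <- function(x, k_range, folds = 5L, seed = 1L,
                     mask_fraction = 0.05, ...) {
  if (length(k_range) == 0L) stop("k_range is empty")
  if (folds < 2L) stop("need at least 2 folds")
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop("mask_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  obs <- which(!is.na(x$calls))
  err <- matrix(NA_real_, length(k_range), folds)
  for (f in seq_len(folds)) {
    masked <- sample(obs, max(1L, round(mask_fraction * length(obs))))
    xm <- x
    xm$calls[masked] <- NA_integer_
    fold_seed <- sample.int(.Machine$integer.max, 1L)
    for (ki in seq_along(k_range)) {
      fit <- admixture_em(xm, k_range[ki], seed = fold_seed, ...)
      pred <- 2 * (fit$Q %*% fit$P)
      err[ki, f] <- mean((x$calls[masked] - pred[masked])^2)
    }
  }
  data.frame(K = k_range, cv_error = rowMeans(err))
}
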