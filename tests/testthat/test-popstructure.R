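test_that("PCA separates diverged groups and matches the dense oracle", {
  sim <- simulate_admixed_genotypes(K = 2, F = 0.2, n = 60, m = 2000,
                                    seed = 17, group_sizes = c(30, 30))
  pc <- snp_pca(sim$genotypes, k = 2)
  g1 <- pc$coordinates[sim$genotypes$samples$pop == "K1", 1]
  g2 <- pc$coordinates[sim$genotypes$samples$pop == "K2", 1]
  expect_true(max(min(g1), min(g2)) > min(max(g1), max(g2)) ||
                max(g1) < min(g2) || max(g2) < min(g1))
  # duplicated samples coincide in PC space
  gm <- sim$genotypes
  gm$calls[2, ] <- gm$calls[1, ]
  pc2 <- snp_pca(gm, k = 3)
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ],
               tolerance = 1e-8)
  # dense-oracle equivalence on a 10 x 20 matrix
  small <- make_gm(hwe_genotypes(10, runif(20, 0.2, 0.8), seed = 71))
  pcs <- snp_pca(small, k = 3)
  p <- colMeans(small$calls) / 2
  poly <- p > 0 & p < 1
  Z <- scale(small$calls[, poly], center = 2 * p[poly],
             scale = sqrt(2 * p[poly] * (1 - p[poly])))
  ev <- eigen(crossprod(Z) / ncol(Z), symmetric = TRUE)$values
  expect_equal(pcs$explained_fraction,
               (ev / sum(ev))[1:3], tolerance = 1e-8)
  expect_error(snp_pca(small, k = 10), "k must be")
})

test_that("PCA scores are invariant to sample order up to sign", {
  gm <- make_gm(hwe_genotypes(15, runif(300, 0.2, 0.8), seed = 23))
  pc <- snp_pca(gm, k = 2)
  perm <- sample(15)
  pc_p <- snp_pca(subset_genotypes(gm, sample_idx = perm), k = 2)
  for (comp in 1:2) {
    a <- pc$coordinates[perm, comp]
    b <- pc_p$coordinates[, comp]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-6)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-6)))
  }
})

test_that("heterozygosity reproduces HWE expectations and detects inbreeding", {
  one <- make_gm(matrix(1L, 10, 1))
  h <- heterozygosity(one)
  expect_equal(h$Ho, 1)
  expect_equal(h$He, 0.5)
  hw <- make_gm(hwe_genotypes(500, runif(400, 0.1, 0.9), seed = 3))
  hh <- heterozygosity(hw)
  expect_equal(hh$Ho, hh$He, tolerance = 0.02)
  # fully inbred: each individual carries two copies of one allele
  set.seed(4)
  inbred <- matrix(2L * rbinom(200 * 50, 1, 0.4), 200, 50)
  hi <- heterozygosity(make_gm(inbred))
  expect_lt(hi$Ho, hi$He)
  expect_equal(hi$Ho, 0)
  expect_error(heterozygosity(make_gm(matrix(0L, 4, 3))), "polymorphic")
})

test_that("Weir-Cockerham Fst matches the literal transcription oracle", {
  # fixed for alternate alleles: complete differentiation
  fixed <- list(make_gm(matrix(0L, 8, 1), pop = "A"),
                make_gm(matrix(2L, 8, 1), pop = "B"))
  fr <- weir_cockerham_fst(fixed)
  expect_equal(fr$per_locus$theta, 1)
  # random split of one population: theta near zero
  hw <- make_gm(hwe_genotypes(80, runif(2000, 0.2, 0.8), seed = 5))
  hw$samples$pop <- rep(c("X", "Y"), 40)
  expect_lt(abs(weir_cockerham_fst(hw)$mean_theta), 0.01)
  # single-locus agreement with the step-by-step oracle, many cases
  set.seed(66)
  for (i in 1:50) {
    n1 <- sample(4:30, 1); n2 <- sample(4:30, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    g2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    if (length(unique(c(g1, g2))) == 1) next
    pair <- list(make_gm(matrix(as.integer(g1), ncol = 1), pop = "A"),
                 make_gm(matrix(as.integer(g2), ncol = 1), pop = "B"))
    got <- weir_cockerham_fst(pair)
    want <- wc_oracle_single_locus(g1, g2)
    expect_equal(got$per_locus$a, want$a, tolerance = 1e-12)
    expect_equal(got$per_locus$b, want$b, tolerance = 1e-12)
    expect_equal(got$per_locus$c, want$c, tolerance = 1e-12)
    if (!is.na(want$theta))
      expect_equal(got$mean_theta, want$theta, tolerance = 1e-12)
  }
  expect_error(weir_cockerham_fst(list(fixed[[1]])), "two populations")
})

test_that("Fst brackets the generating divergence on Balding-Nichols draws", {
  for (f_true in c(0.05, 0.2)) {
    reps <- vapply(1:8, function(s) {
      sim <- simulate_admixed_genotypes(K = 2, F = f_true, n = 100,
                                        m = 2000, seed = 900 + s,
                                        group_sizes = c(50, 50))
      weir_cockerham_fst(sim$genotypes)$mean_theta
    }, numeric(1))
    expect_gt(f_true, quantile(reps, 0.025) - 0.01)
    expect_lt(f_true, quantile(reps, 0.975) + 0.01)
  }
})

test_that("admixture EM is exact at K = 1 and recovers pure groups", {
  gm <- make_gm(hwe_genotypes(30, runif(200, 0.2, 0.8), seed = 12))
  fit1 <- admixture_em(gm, K = 1, seed = 2)
  expect_equal(unname(fit1$Q[, 1]), rep(1, 30))
  phat <- colMeans(gm$calls) / 2
  expect_equal(unname(fit1$P[1, ]), unname(phat), tolerance = 1e-6)
  ll_closed <- sum(dbinom(gm$calls, 2, rep(phat, each = 30), log = TRUE))
  expect_equal(max(fit1$loglik_trace), ll_closed, tolerance = 1e-6)

  sim <- simulate_admixed_genotypes(K = 2, F = 0.1, alpha = 0.02, n = 80,
                                    m = 2500, seed = 7)
  fit <- admixture_em(sim$genotypes, K = 2, seed = 19)
  al <- align_q_matrices(fit$Q, sim$truth$Q)
  expect_lt(al$mae, 0.05)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, 80), tolerance = 1e-8)
  expect_error(admixture_em(gm, K = 31), "exceed")
})

test_that("EM log-likelihood never decreases across random data sets", {
  for (s in 1:4) {
    sim <- simulate_admixed_genotypes(K = 3, F = 0.05, alpha = 0.7,
                                      n = 25, m = 150, seed = s)
    fit <- admixture_em(sim$genotypes, K = sample(1:4, 1), seed = s,
                        max_iter = 80)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
  }
})

test_that("cross-validated K selection finds strong structure", {
  sim <- simulate_admixed_genotypes(K = 3, F = 0.3, n = 60, m = 600,
                                    seed = 31,
                                    group_sizes = c(20, 20, 20))
  cv <- select_k(sim$genotypes, k_range = 1:5, folds = 3, seed = 8)
  best <- cv$K[which.min(cv$cv_error)]
  expect_true(best %in% 2:4)
  # panmictic data: K > 1 brings no real improvement
  pan <- simulate_admixed_genotypes(K = 1, F = 0, n = 50, m = 500, seed = 2)
  cv1 <- select_k(pan$genotypes, k_range = c(1, 3), folds = 3, seed = 9)
  e1 <- cv1$cv_error[cv1$K == 1]
  expect_lt((e1 - min(cv1$cv_error)) / e1, 0.02)
  expect_error(select_k(sim$genotypes, 1:2, folds = 1), "folds")
  expect_error(select_k(sim$genotypes, 1:2, folds = 3, mask_fraction = 0),
               "mask_fraction")
})
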