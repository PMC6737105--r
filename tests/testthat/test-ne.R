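test_that("sample-size adjustment is the stated arithmetic", {
  expect_equal(adjust_r2(1 / 55, 55), 0)
  expect_equal(adjust_r2(0.06, 55), 0.06 - 1 / 55)
  expect_equal(adjust_r2(0.01, 55), 0.01 - 1 / 55)  # negative passthrough
  expect_lt(adjust_r2(0.01, 55), 0)
  expect_error(adjust_r2(0.1, 1), ">= 2")
})

test_that("the Sved inversion matches hand arithmetic and rejects bad bins", {
  expect_equal(sved_ne(0.05, 0.025, alpha = 2), (20 - 2) / 0.1)
  expect_equal(sved_ne(0.05, 0.025, alpha = 2), 180)
  expect_true(is.na(sved_ne(0.5, 0.025, alpha = 2)))   # 1/r2 == alpha
  expect_true(is.na(sved_ne(-0.01, 0.025)))
  expect_error(sved_ne(0.05, 0.6), "c_t")
  # algebraic round trip
  for (i in 1:25) {
    ne <- runif(1, 10, 1000); cc <- runif(1, 1e-4, 0.5); al <- runif(1, 1, 2.5)
    r2 <- 1 / (al + 4 * cc * ne)
    expect_equal(sved_ne(r2, cc, alpha = al), ne, tolerance = 1e-10)
  }
})

test_that("mapping functions behave at small and large distance", {
  h <- mapping_function("haldane")
  sf <- mapping_function("sved_feldman")
  expect_equal(h(1e-4), 1e-4, tolerance = 1e-3)
  expect_lt(h(10), 0.5 + 1e-12)
  expect_equal(sf(0.01), 0.01 / 1.02)
})

test_that("harmonic means and the segment arithmetic are exact", {
  expect_equal(harmonic_mean_ne(c(7, 7, 7)), 7)
  expect_equal(harmonic_mean_ne(c(100, 300)), 150)
  set.seed(2)
  v <- runif(20, 10, 500)
  expect_lte(harmonic_mean_ne(v), mean(v))
  expect_error(harmonic_mean_ne(c(10, -1)), "positive")

  me <- effective_segments(159, 14.8)
  expect_equal(me$Me, 9412.8)
  expect_equal(me$Me_rounded, 9400)
  expect_equal(effective_segments(78, 14.8)$Me_rounded, 4600)
  expect_equal(effective_segments(2 * 78, 14.8)$Me, 2 * 4617.6)  # linear
  req <- marker_requirements(78, 14.8)
  expect_equal(req$markers_10NeL_rounded, 11500)
  expect_equal(req$individuals_2NeL, req$markers_10NeL / 5)
  expect_error(marker_requirements(-1, 14.8), "positive")
})

test_that("a constructed flat pair set yields a flat trajectory", {
  ne_star <- 120
  S <- 55
  bin_size <- 50000
  pairs <- do.call(rbind, lapply(1:30, function(b) {
    mid <- (b - 0.5) * bin_size
    cc <- mid * 1e-8
    r2 <- 1 / (2 + 4 * cc * ne_star) + 1 / S
    data.frame(chrom = "chr1", id_i = "x", id_j = "y",
               pos_i = 0L, pos_j = 0L,
               distance_bp = rep(mid, 60), r2 = r2,
               estimator = "composite")
  }))
  traj <- historical_ne(pairs, S = S, settings = ne_settings(alpha = 2))
  expect_equal(traj$points$Ne, rep(ne_star, 30), tolerance = 1e-9)
  expect_equal(traj$harmonic_overall, ne_star, tolerance = 1e-9)
  # t = 1/(2c): smaller distances probe older generations
  expect_equal(traj$points$t[which.max(traj$points$c)],
               min(traj$points$t))
  expect_true(all(diff(traj$points$t) > 0))
  # bins below the pair-count floor are dropped with a log message
  thin <- pairs[c(which(pairs$distance_bp < 0.5e6),
                  which(pairs$distance_bp >= 0.5e6)[seq(1, 900, by = 3)]), ]
  expect_message(tr2 <- historical_ne(thin, S = S,
                                      settings = ne_settings(min_pairs = 50)),
                 "dropped")
  expect_lt(nrow(tr2$points), 30)
})

test_that("regression extrapolation of the trajectory is plain OLS", {
  flat <- data.frame(t = c(5, 20, 50), Ne = c(120, 120, 120))
  expect_equal(regress_contemporary(flat), 120)
  two <- data.frame(t = c(5, 15), Ne = c(100, 200))
  # line through the two points: slope 10, intercept 50, so 60 at t = 1
  expect_equal(regress_contemporary(two), 60)
  expect_equal(regress_contemporary(two[2:1, ]), 60)  # order invariant
  expect_error(regress_contemporary(two[1, , drop = FALSE]), ">= 2")
  down <- data.frame(t = c(5, 15), Ne = c(30, 200))
  expect_error(regress_contemporary(down), "non-positive")
})

test_that("contemporary Ne screening and invariances hold", {
  gm <- make_gm(hwe_genotypes(40, runif(60, 0.2, 0.45), seed = 4),
                chrom = rep(c("chr1", "chr2", "chr3"), each = 20))
  est <- contemporary_ne_ld(gm, mating = "random")
  # marker order invariance
  perm <- sample(60)
  gm_p <- subset_genotypes(gm, variant_idx = perm)
  expect_equal(contemporary_ne_ld(gm_p, mating = "random")$ne, est$ne,
               tolerance = 1e-9)
  # allele relabeling invariance
  gm_f <- gm
  gm_f$calls[, 10] <- 2L - gm_f$calls[, 10]
  expect_equal(contemporary_ne_ld(gm_f, mating = "random")$ne, est$ne,
               tolerance = 1e-9)
  expect_error(contemporary_ne_ld(gm, pcrit = 0.499), "pcrit")
  expect_error(contemporary_ne_ld(subset_genotypes(gm, sample_idx = 1:5)),
               ">= 10")
})

test_that("contemporary Ne rises with the simulated census size", {
  est_at <- function(N, seeds) {
    vapply(seeds, function(s) {
      sim <- quick_wf(seed = s, N = N, n_ind = 40, gens = 120,
                      density = 12.5)
      qc <- apply_qc(sim$genotypes)
      contemporary_ne_ld(qc$genotypes, mating = "monogamy")$ne
    }, numeric(1))
  }
  lo <- est_at(50, 700 + 1:4)
  hi <- est_at(150, 700 + 1:4)
  expect_lt(median(lo), median(hi))
})
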