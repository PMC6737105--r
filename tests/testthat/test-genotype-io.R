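test_that("genotype_matrix enforces its invariants", {
  expect_error(make_gm(matrix(3L, 1, 1)), "calls must be in")
  gm <- make_gm(rbind(c(0, 1), c(2, NA)))
  expect_equal(n_samples(gm), 2L)
  expect_equal(n_variants(gm), 2L)
  # variants are sorted by position within chromosome
  g2 <- genotype_matrix(matrix(c(1L, 0L), 1),
                        data.frame(chrom = "chr1", pos = c(500L, 100L),
                                   id = c("b", "a"), ref = "A", alt = "C"),
                        data.frame(id = "s1", pop = "P"))
  expect_equal(g2$variants$pos, c(100L, 500L))
  expect_equal(unname(g2$calls[1, ]), c(0L, 1L))
})

test_that("hand-written VCF records decode to the right dosages", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=1000>",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1"), collapse = "\t"),
           "chr1\t10\tv1\tA\tC\t.\tPASS\t.\tGT\t0/1",
           "chr1\t20\tv2\tA\tC\t.\tPASS\t.\tGT\t./.",
           "chr1\t30\tv3\tA\tC,G\t.\tPASS\t.\tGT\t0/1",
           "chr1\t40\tv4\tA\tC\t.\tPASS\t.\tGT\t1|1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(gm <- read_vcf(f), "skipped")
  expect_equal(n_variants(gm), 3L)                 # multiallelic dropped
  expect_equal(unname(gm$calls[1, ]), c(1L, NA, 2L))
  expect_error(read_vcf("/nonexistent/file.vcf"), "no such file")
})

test_that("VCF and PLINK round trips are lossless and agree", {
  cfg <- sim_config(n_individuals = 15, n_chromosomes = 2,
                    chrom_length_bp = 3e6, marker_density = 15,
                    ne_trajectory = data.frame(generation = 1, N = 25),
                    n_generations = 8, missing_rate = 0.05, seed = 31)
  g <- simulate_wf_population(cfg)$genotypes
  vf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, vf)
  g_vcf <- read_vcf(vf, pop = "SIM")
  expect_identical(unname(g_vcf$calls), unname(g$calls))
  expect_identical(g_vcf$variants$pos, g$variants$pos)
  expect_identical(g_vcf$variants$id, g$variants$id)

  pf <- withr::local_tempfile(fileext = ".ped")
  mf <- withr::local_tempfile(fileext = ".map")
  write_plink_text(g, pf, mf)
  g_ped <- read_plink_text(pf, mf, alt_alleles = g$variants$alt)
  expect_identical(unname(g_ped$calls), unname(g_vcf$calls))
  expect_identical(g_ped$variants$pos, g_vcf$variants$pos)
})

test_that("PED allele pairs convert to dosage with 0 meaning missing", {
  pf <- withr::local_tempfile(fileext = ".ped")
  mf <- withr::local_tempfile(fileext = ".map")
  writeLines(c("chr1\tv1\t0\t100", "chr1\tv2\t0\t200"), mf)
  writeLines(c("F1 s1 0 0 0 -9 C C A A",
               "F1 s2 0 0 0 -9 0 0 A C"), pf)
  g <- read_plink_text(pf, mf, alt_alleles = c("C", "C"))
  expect_equal(unname(g$calls[1, ]), c(2L, 0L))
  expect_equal(unname(g$calls[2, ]), c(NA_integer_, 1L))
  writeLines(c("F1 s1 0 0 0 -9 C C"), pf)
  expect_error(read_plink_text(pf, mf), "MAP lists")
})

test_that("marker intersection matches brute-force set algebra", {
  base <- hwe_genotypes(10, runif(30, 0.2, 0.8), seed = 8)
  mk <- function(keep, pop) {
    gm <- make_gm(base[, keep, drop = FALSE], pos = (keep) * 1000L,
                  pop = pop)
    gm
  }
  a <- mk(1:20, "A"); b <- mk(5:25, "B"); c <- mk(10:30, "C")
  ps <- intersect_markers(list(A = a, B = b, C = c))
  expect_equal(ps$n_common, length(intersect(intersect(1:20, 5:25), 10:30)))
  cols <- c("chrom", "pos", "ref", "alt")
  expect_identical(ps$populations$A$variants[, cols],
                   ps$populations$B$variants[, cols])
  # commutative and idempotent
  ps2 <- intersect_markers(list(C = c, A = a, B = b))
  expect_equal(ps2$n_common, ps$n_common)
  expect_setequal(ps2$populations$A$variants$pos, ps$populations$A$variants$pos)
  again <- intersect_markers(ps$populations)
  expect_equal(again$n_common, ps$n_common)
  # identity and empty cases
  solo <- intersect_markers(list(a))
  expect_equal(solo$n_common, n_variants(a))
  expect_error(intersect_markers(list(mk(1:5, "A"), mk(10:15, "B"))),
               "no markers shared")
})

test_that("truth sidecars and key-value configs round trip", {
  sim <- simulate_admixed_genotypes(K = 2, F = 0.1, n = 8, m = 12, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sim_truth(sim$truth, f)
  back <- read_sim_truth(f)
  expect_equal(back$Q, sim$truth$Q, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$P, sim$truth$P, tolerance = 1e-12, ignore_attr = TRUE)

  cf <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("maf_min = 0.05", "# comment", "pops = A, B, C",
               "lengths = 1e6, 2e6"), cf)
  cfg <- read_keyvalue_config(cf)
  expect_equal(cfg$maf_min, 0.05)
  expect_equal(cfg$pops, c("A", "B", "C"))
  expect_equal(cfg$lengths, c(1e6, 2e6))
})
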