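test_that("a toy VCF loads with shapes, missingness and depths intact", {
  path <- tempfile(fileext = ".vcf")
  writeToyVcf(path, rbind(c("0/1:3,2", "0/0:9,0", "./.:0,0"),
                          c("1/1:0,7", "0/1:4,11", "0/0:12,0")),
              pos = c(100, 250))
  gm <- readGenotypeVcf(path)
  expect_s4_class(gm, "GenotypeMatrix")
  expect_equal(dim(gm), c(2L, 3L))
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  expect_true(is.na(g1[1, 3]))               # ./. is missing, not reference
  expect_equal(g1[2, 1], 1L)
  ad <- SummarizedExperiment::assay(gm, "AD")
  expect_equal(unname(ad[1, 1, 1:2]), c(3, 2))   # AD=3,2 stored per allele
  expect_equal(unname(ad[2, 2, 1:2]), c(4, 11))
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(gm)),
               c(100L, 250L))
  expect_error(readGenotypeVcf(tempfile()), "no such file")
})

test_that("depth, quality and presence filters invalidate and drop as stated", {
  # defaults: >= 5 reads per called allele, PHRED >= 30, >= 80% presence
  path <- tempfile(fileext = ".vcf")
  gt <- rbind(
    c("0/1:20,20", "0/0:40,0", "1/1:0,40", "0/1:20,20", "0/0:40,0"), # clean
    c("0/1:4,11",  "0/0:40,0", "1/1:0,40", "0/1:20,20", "0/0:40,0"), # het w/ 4x allele
    c("0/1:20,20", "0/0:40,0", "1/1:0,40", "0/1:20,20", "0/0:40,0"), # low qual site
    c("./.:0,0",   "./.:0,0",  "1/1:0,40", "0/1:20,20", "0/0:40,0")) # 60% present
  writeToyVcf(path, gt, qual = c(60, 60, 20, 60))
  gm <- readGenotypeVcf(path)
  out <- filterSites(gm)
  rep <- out$report
  # clean site retained unchanged
  expect_equal(rownames(out$genotypes)[1], "chr1:1")
  g1 <- SummarizedExperiment::assay(out$genotypes, "GT1")
  expect_equal(sum(is.na(g1["chr1:1", ])), 0)
  # the 4x-supported heterozygote was set missing (one allele below 5x)
  expect_true(is.na(g1["chr1:2", 1]))
  expect_equal(rep$removed[rep$filter == "allele_depth"], 1)
  # PHRED 20 site: all genotypes invalidated, so presence drops the site;
  # the 60%-present site is dropped outright (0.6 < 0.8)
  expect_false("chr1:3" %in% rownames(out$genotypes))
  expect_false("chr1:4" %in% rownames(out$genotypes))
  expect_equal(rep$removed[rep$filter == "presence"], 2)
  # report arithmetic: removed + retained = input for every rule
  expect_true(all(rep$input == rep$removed + rep$retained))
  expect_error(filterSites(gm, minPresence = 1.5), "thresholds")
})

test_that("filtering is idempotent", {
  sim <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 8,
                                            nAutosomalSites = 250,
                                            missingRate = 0.1, seed = 5))
  once <- filterSites(sim$genotypes)
  twice <- filterSites(once$genotypes)
  expect_equal(nrow(twice$genotypes), nrow(once$genotypes))
  expect_equal(sum(twice$report$removed), 0)
})

test_that("biallelic extraction drops monomorphic and multi-allelic sites", {
  path <- tempfile(fileext = ".vcf")
  writeToyVcf(path, rbind(c("0/1:20,20", "0/2:20,20"),   # tri-allelic
                          c("0/0:40,0",  "0/0:40,0"),    # monomorphic
                          c("0/1:20,20", "0/0:40,0"),    # biallelic singleton
                          c("0/1:20,20", "1/1:0,40")),
              alt = c("T,G", "T", "T", "T"))
  gm <- readGenotypeVcf(path)
  out <- extractBiallelicSnps(gm)
  expect_equal(rownames(out), c("chr1:3", "chr1:4"))  # singleton retained
  # a site monomorphic only after invalidation is also removed
  gm2 <- makeGm(rbind(c("0/1", "0/0"), c("0/1", "0/0")),
                adRef = matrix(c(4, 40, 40, 40), 2),
                adAlt = matrix(c(4, 40, 40, 40), 2))
  f <- filterSites(gm2)$genotypes
  expect_equal(rownames(extractBiallelicSnps(f)), "chr1:2")
})

test_that("exact HWE test matches direct factorial enumeration", {
  # all genotype-count triples at a spread of sample sizes up to 25
  for (n in c(4, 7, 12, 25)) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hweExactP(nAA, nAa, naa), hweOracleP(nAA, nAa, naa),
                   tolerance = 1e-10,
                   label = sprintf("counts (%d,%d,%d)", nAA, nAa, naa))
    }
  }
  # canonical cases
  expect_gt(hweExactP(25, 50, 25), 0.5)       # perfect proportions
  expect_lt(hweExactP(50, 0, 50), 1e-20)      # complete het deficit
  expect_true(is.na(hweExactP(30, 0, 0)))     # monomorphic: undefined
})

test_that("HWE screening is population-aware", {
  # two populations in internal HWE at different frequencies: pooling them
  # would fake disequilibrium (Wahlund effect), per-population testing must not
  n <- 40
  gtA <- c(rep("1/1:0,40", 36), rep("0/1:20,20", 4))         # p ~ 0.95
  gtB <- c(rep("0/0:40,0", 36), rep("0/1:20,20", 4))         # p ~ 0.05
  path <- tempfile(fileext = ".vcf")
  writeToyVcf(path, matrix(c(gtA, gtB), nrow = 1))
  gm <- readGenotypeVcf(path)
  pops <- rep(c("A", "B"), each = n)
  scr <- hweScreen(gm, pops)
  expect_false(any(scr$flagged))
  pooled <- hweScreen(gm, rep("all", 2 * n))
  expect_true(any(pooled$flagged))            # the pooled test would flag
  # a genuine het-deficit site is flagged within one population
  bad <- c(rep("0/0:40,0", 20), rep("1/1:0,40", 20))
  path2 <- tempfile(fileext = ".vcf")
  writeToyVcf(path2, matrix(c(bad, gtB), nrow = 1))
  scr2 <- hweScreen(readGenotypeVcf(path2), pops)
  expect_true(scr2$flagged[1])
  expect_error(hweScreen(gm, pops[-1]), "population")
})
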