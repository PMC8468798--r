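test_that("constant-size simulator reproduces closed-form spectra", {
  const <- EpochModel(v = 1, t = 0.5)
  # n = 2: E[xi_1] = theta
  s2 <- simulateSfs1d(2, const, theta = 1, reps = 2e4, seed = 1)
  se <- attr(s2, "se")
  expect_lt(abs(sfsEntries(s2)[2] - 1), 3 * se[2])
  # n = 10: total = theta * sum 1/i (Watterson), and each class ~ theta/i
  s10 <- simulateSfs1d(10, const, theta = 5, reps = 2e4, seed = 2)
  m <- sfsEntries(s10)[2:10]
  se <- attr(s10, "se")[2:10]
  expect_lt(abs(sum(m) - 5 * sum(1 / (1:9))), 3 * sqrt(sum(se^2)))
  expect_true(all(abs(m - 5 / (1:9)) < 4 * se))
})

test_that("a recent tenfold expansion enriches singletons", {
  s <- simulateSfs1d(10, EpochModel(v = 10, t = 0.1), theta = 1,
                     reps = 2e4, seed = 3)
  m <- sfsEntries(s)
  expect_gt(m[2] / m[3], 2.0)   # constant-model ratio is exactly 2
})

test_that("seed determinism is bit-for-bit", {
  m <- EpochModel(v = c(0.5, 3), t = c(0.2, 0.1))
  a <- simulateSfs1d(8, m, theta = 2, reps = 500, seed = 99)
  b <- simulateSfs1d(8, m, theta = 2, reps = 500, seed = 99)
  expect_identical(sfsEntries(a), sfsEntries(b))
  d1 <- StudyDesign(nSamplesPerGroup = 4, nAutosomalSites = 80,
                    nZSites = 20, seed = 7)
  x <- simulateGenotypeMatrix(d1)
  y <- simulateGenotypeMatrix(d1)
  expect_identical(SummarizedExperiment::assay(x$genotypes, "GT1"),
                   SummarizedExperiment::assay(y$genotypes, "GT1"))
  expect_identical(SummarizedExperiment::assay(x$genotypes, "AD"),
                   SummarizedExperiment::assay(y$genotypes, "AD"))
  z <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 4,
                                          nAutosomalSites = 80,
                                          nZSites = 20, seed = 8))
  expect_false(identical(SummarizedExperiment::assay(x$genotypes, "GT1"),
                         SummarizedExperiment::assay(z$genotypes, "GT1")))
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(simulateSfs1d(1, EpochModel(v = 1, t = 1), 1), "n must")
  expect_error(simulateSfs1d(5, EpochModel(v = 1, t = 1), -2), "theta")
  expect_error(EpochModel(v = c(1, -1), t = c(1, 1)), "positive")
  expect_error(simulateSfs2d(4, 4, "made_up_model"), "unknown pairwise model")
  expect_error(StudyDesign(nSamplesPerGroup = 4, nAutosomalSites = 10,
                           missingRate = 1.2), "missingRate")
})

test_that("panmictic joint spectra are exchange-symmetric", {
  s <- simulateSfs2d(4, 4, "neutral_no_divergence", theta = 1,
                     reps = 2e4, seed = 5)
  m <- sfsEntries(s)
  se <- attr(s, "se")
  off <- abs(m - t(m))
  tol <- 3 * sqrt(se^2 + t(se)^2 + 1e-12)
  expect_true(all(off <= tol))
})

test_that("deep splits without migration lose shared polymorphism", {
  shared <- vapply(c(0.1, 1, 5), function(Tsplit) {
    s <- simulateSfs2d(6, 6, "split_no_migration", c(1, 1, Tsplit),
                       theta = 1, reps = 1e4, seed = 11)
    m <- sfsEntries(s)
    # polymorphic in both demes simultaneously
    sum(m[2:6, 2:6]) / sum(m)
  }, 0)
  expect_true(all(diff(shared) < 0))
  expect_lt(shared[3], 0.05)
})

test_that("strong symmetric migration converges to the panmictic spectrum", {
  pan <- simulateSfs2d(4, 4, "neutral_no_divergence", theta = 1,
                       reps = 3e4, seed = 21)
  kd <- vapply(c(1, 3, 10), function(m) {
    s <- simulateSfs2d(4, 4, "split_migration", c(0.5, 0.5, 2, m),
                       theta = 1, reps = 3e4, seed = 22)
    max(abs(sfsEntries(s) - sfsEntries(pan)))
  }, 0)
  expect_true(all(diff(kd) < 0))   # Kolmogorov-style distance shrinks in m
  expect_lt(kd[3], 0.1)
})

test_that("the genotype emulator honours its design knobs", {
  # all-male design: unit Z/autosome depth ratio (homogametic males)
  male <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 8,
                                             nGroups = 1,
                                             nAutosomalSites = 300,
                                             nZSites = 150, sexRatio = 0,
                                             missingRate = 0, seed = 13))
  ad <- SummarizedExperiment::assay(male$genotypes, "AD")
  depth <- ad[, , 1] + ad[, , 2]
  isZ <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(male$genotypes))) == "chrZ"
  ratio <- colMeans(depth[isZ, ]) / colMeans(depth[!isZ, ])
  expect_true(all(abs(ratio - 1) < 0.1))
  # zero missingness
  expect_false(anyNA(SummarizedExperiment::assay(male$genotypes, "GT1")))
  # truth object accompanies the dataset and matches its dimensions
  expect_s4_class(male$truth, "SimTruth")
  expect_equal(length(male$truth@sex), ncol(male$genotypes))
  expect_equal(nrow(male$truth@alleleFreqs), nrow(male$genotypes))
  # fixed differences between groups push Phi_ST to exactly 1
  fixed <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 6,
                                              nGroups = 2,
                                              nAutosomalSites = 150,
                                              groupAlleleFreqDivergence = 1,
                                              missingRate = 0, sexRatio = 0,
                                              seed = 14))
  res <- phiSt(fixed$genotypes, fixed$truth@group)
  expect_equal(res$composite, 1.0)
  # median per-sample depth sits near the design target of 119 reads
  expect_lt(abs(median(depth) - 119), 6)
})
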