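test_that("alt-allele counts are tallied into the unfolded spectrum", {
  # 2 diploid samples = 4 haploid copies; alt counts {1, 1, 2, 3}
  gm <- makeGm(rbind(c("0/0", "0/1"),
                     c("0/1", "0/0"),
                     c("0/1", "0/1"),
                     c("1/1", "0/1")))
  sfs <- buildSfs1d(gm)
  expect_equal(sfsEntries(sfs), c(0, 2, 1, 1, 0))
  expect_false(isFolded(sfs))
  expect_equal(seqLength(sfs), 4)
})

test_that("folding pools complementary classes and preserves the total", {
  sfs <- Sfs1D(c(0, 2, 1, 1, 0))
  f <- fold(sfs)
  expect_equal(sfsEntries(f), c(0, 3, 1, 0, 0))
  expect_true(isFolded(f))
  expect_equal(sum(sfsEntries(f)), sum(sfsEntries(sfs)))
  # worked example with distinct masses
  f2 <- fold(Sfs1D(c(0, 5, 2, 3, 0)))
  expect_equal(sfsEntries(f2)[1:3], c(0, 8, 2))
  # idempotence with a warning
  expect_warning(f3 <- fold(f2), "already folded")
  expect_equal(sfsEntries(f3), sfsEntries(f2))
})

test_that("2D folding conserves the total and aggregates complements", {
  e <- matrix(1, 3, 3)  # n1 = n2 = 2, all-ones
  s <- Sfs2D(e)
  f <- fold(s)
  expect_equal(sum(sfsEntries(f)), sum(e))
  expect_true(isFolded(f))
  # cell (0,1) aggregates (0,1) and (2,1)
  expect_equal(sfsEntries(f)[1, 2], 2)
})

test_that("random 2D spectra fold losslessly", {
  set.seed(4)
  for (dims in list(c(4, 6), c(5, 5), c(3, 8))) {
    e <- matrix(rpois((dims[1] + 1) * (dims[2] + 1), 5), dims[1] + 1)
    f <- fold(Sfs2D(e))
    expect_equal(sum(sfsEntries(f)), sum(e))
    # everything beyond the fold is zeroed
    tot <- outer(0:dims[1], 0:dims[2], "+")
    expect_true(all(sfsEntries(f)[2 * tot > sum(dims)] == 0))
  }
})

test_that("masking removes singleton and fixed classes and is idempotent", {
  f <- applyMask(fold(Sfs1D(c(3, 5, 2, 3, 1, 8, 0, 0, 0, 1, 2))))  # n = 10
  expect_true(all(sfsMask(f)[1:2]))
  expect_false(any(sfsMask(f)[3:6]))
  expect_identical(sfsMask(applyMask(f)), sfsMask(f))
  u <- applyMask(Sfs1D(c(3, 5, 2, 3, 1, 8, 0, 0, 0, 1, 2)))
  expect_true(all(sfsMask(u)[c(1, 2, 10, 11)]))
  expect_error(applyMask(f, rule = "everything"), "unknown masking rule")
  # unmasked count equals S minus the masked classes
  expect_equal(sum(sfsEntries(f)[!sfsMask(f)]),
               sum(sfsEntries(f)) - sum(sfsEntries(f)[sfsMask(f)]))
})

test_that("missing genotypes are dropped or hypergeometrically projected", {
  gm <- makeGm(rbind(c("0/1", "0/1"),
                     c("0/1", "./."),   # 1 of 2 genotypes called
                     c("1/1", "0/0")))
  # default: incomplete sites dropped
  sfs <- buildSfs1d(gm)
  expect_equal(seqLength(sfs), 2)
  expect_equal(sfsEntries(sfs), c(0, 0, 2, 0, 0))
  # projection 4 -> 2: enumerate subsamples of the called alleles
  p <- buildSfs1d(gm, projectionN = 2)
  # site1: x=2 of 4 -> weights dhyper(0:2, 2, 2, 2) = (1/6, 4/6, 1/6)
  # site2: x=1 of 2 -> (0, 1, 0); site3: x=2 of 4 -> as site1
  expect_equal(sfsEntries(p), c(2 / 6, 1 + 8 / 6, 2 / 6))
  expect_equal(sum(sfsEntries(p)), 3)  # weights sum to one per site
})

test_that("projection to the full sample size is the identity", {
  sim <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 6,
                                            nAutosomalSites = 400,
                                            nGroups = 1, missingRate = 0,
                                            sexRatio = 0, seed = 30))
  gm <- extractBiallelicSnps(sim$genotypes)
  expect_equal(sfsEntries(buildSfs1d(gm, projectionN = 12)),
               sfsEntries(buildSfs1d(gm)))
  # with missing data every projected site still contributes unit mass
  sim2 <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 6,
                                             nAutosomalSites = 400,
                                             nGroups = 1, missingRate = 0.2,
                                             sexRatio = 0, seed = 31))
  gm2 <- extractBiallelicSnps(sim2$genotypes)
  p <- buildSfs1d(gm2, projectionN = 8)
  expect_equal(sum(sfsEntries(p)), seqLength(p))
  expect_error(buildSfs1d(gm2, projectionN = 40), "projection")
})

test_that("SFS text round-trip is bit-exact for integer spectra", {
  path <- tempfile(fileext = ".fs")
  s <- applyMask(fold(Sfs1D(c(0, 7, 3, 2, 0), L = 1234)))
  writeSfs(s, path)
  r <- readSfs(path)
  expect_identical(sfsEntries(r), sfsEntries(s))
  expect_identical(sfsMask(r), sfsMask(s))
  expect_identical(isFolded(r), isFolded(s))
  expect_identical(seqLength(r), 1234)
  # 2D
  e <- matrix(rpois(5 * 7, 20), 5, 7)
  s2 <- applyMask(Sfs2D(e, L = 99))
  path2 <- tempfile(fileext = ".fs")
  writeSfs(s2, path2)
  r2 <- readSfs(path2)
  expect_identical(sfsEntries(r2), sfsEntries(s2))
  expect_identical(sfsMask(r2), sfsMask(s2))
  expect_identical(seqLength(r2), 99)
})

test_that("round trip through VCF reproduces the builder's spectrum", {
  sim <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 5,
                                            nAutosomalSites = 200,
                                            nGroups = 1, missingRate = 0,
                                            sexRatio = 0, seed = 12))
  gm <- extractBiallelicSnps(sim$genotypes)
  vcf <- tempfile(fileext = ".vcf.gz")
  writeGenotypeVcf(gm, vcf)
  gm2 <- readGenotypeVcf(vcf)
  expect_equal(sfsEntries(buildSfs1d(gm2)), sfsEntries(buildSfs1d(gm)))
})
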