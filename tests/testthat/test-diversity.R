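test_that("pi on explicit sequences: worked values", {
  # two sequences differing at 1 of 10 sites
  a <- ape::as.DNAbin(matrix(c(strsplit("acgtacgtac", "")[[1]],
                               strsplit("acgtacgtaT", "")[[1]]),
                             2, byrow = TRUE))
  expect_equal(nucleotideDiversity(a)$pi, 0.1)
  # identical sequences
  b <- ape::as.DNAbin(matrix(rep(strsplit("acgtacgtac", "")[[1]], 3),
                             3, byrow = TRUE))
  expect_equal(nucleotideDiversity(b)$pi, 0)
})

test_that("pi on genotypes matches the brute-force mean over allele pairs", {
  # 4 diploid samples at one biallelic site, p = 0.5, complete data
  gm <- makeGm(matrix(c("0/0", "0/1", "1/1", "0/1"), 1))
  got <- nucleotideDiversity(gm)
  alleles <- c(0, 0, 0, 1, 1, 1, 0, 1)
  D <- alleleDistMatrix(alleles)
  brute <- mean(D[lower.tri(D)])
  expect_equal(got$pi[got$locus == "concatenated"], brute)
  expect_equal(brute, 2 * 0.5 * 0.5 * 8 / 7)  # 2p(1-p) * 2n/(2n-1)
  # all-missing site is NA-dropped from the callable length
  gm2 <- makeGm(rbind(c("0/1", "0/1"), c("./.", "./.")))
  expect_equal(nucleotideDiversity(gm2)$L, c(1, 1))
  # a fully uncallable matrix reports NA, not zero
  gm3 <- makeGm(matrix("./.", 2, 2))
  expect_true(is.na(nucleotideDiversity(gm3)$pi))
})

test_that("genotype-path pi equals sequence-path pi on complete data", {
  set.seed(21)
  n <- 6; nSite <- 40
  alleles <- matrix(rbinom(2 * n * nSite, 1, 0.4), nSite, 2 * n)
  gt <- matrix(paste0(alleles[, seq(1, 2 * n, 2)], "/",
                      alleles[, seq(2, 2 * n, 2)]), nSite, n)
  gm <- makeGm(gt)
  piG <- nucleotideDiversity(gm)
  # same data as explicit haploid sequences (a/c code 0/1)
  seqs <- ape::as.DNAbin(t(matrix(c("a", "c")[alleles + 1], nSite, 2 * n)))
  piS <- nucleotideDiversity(seqs)
  expect_equal(piG$pi[piG$locus == "concatenated"] *
                 piG$L[piG$locus == "concatenated"] / nSite,
               piS$pi, tolerance = 1e-12)
})

test_that("Phi_ST equals the brute-force AMOVA decomposition", {
  # two populations of 4 haplotypes each over 5 sites (worked fixture)
  seqs <- c("aaaaa", "aaaat", "aacat", "aaaaa",
            "ttgcc", "ttgcc", "atgcc", "ttgca")
  m <- ape::as.DNAbin(t(vapply(strsplit(seqs, ""), identity,
                               character(5))))
  pops <- rep(c("p1", "p2"), each = 4)
  got <- phiSt(m, pops)
  D <- as.matrix(ape::dist.dna(m, model = "N", pairwise.deletion = TRUE))
  expect_equal(got$raw, phiOracle(D, pops), tolerance = 1e-12)
  # fixed differences at every site
  fixed <- makeGm(matrix(rep(c("0/0", "1/1"), each = 3), 2, 6, byrow = TRUE))
  expect_equal(phiSt(fixed, rep(c("A", "B"), each = 3))$composite, 1.0)
  # identical haplotype frequencies
  same <- makeGm(matrix(rep(c("0/0", "0/1", "1/1"), 2), 2, 6, byrow = TRUE))
  expect_equal(phiSt(same, rep(c("A", "B"), 3))$composite, 0.0)
})

test_that("genotype-mode Phi_ST matches the allele-pair distance oracle", {
  set.seed(31)
  for (rep in 1:5) {
    x1 <- sample(0:8, 1); x2 <- sample(0:8, 1)
    if (x1 == x2) x2 <- (x2 + 3) %% 9
    a1 <- c(rep(1, x1), rep(0, 8 - x1))
    a2 <- c(rep(1, x2), rep(0, 8 - x2))
    gt <- matrix(paste0(c(a1[c(TRUE, FALSE)], a2[c(TRUE, FALSE)]), "/",
                        c(a1[c(FALSE, TRUE)], a2[c(FALSE, TRUE)])), 1)
    gm <- makeGm(gt)
    pops <- rep(c("A", "B"), each = 4)
    got <- phiSt(gm, pops)
    brute <- phiOracle(alleleDistMatrix(c(a1, a2)), rep(c("A", "B"), each = 8))
    expect_equal(got$perSite$phiSt[1], brute, tolerance = 1e-12)
  }
})

test_that("Phi_ST is invariant under population relabeling and ~0 on panmixia", {
  # independent panmictic cohorts, each randomly split into two labels:
  # the raw among/(among+within) ratio averages to zero
  set.seed(99)
  vals <- vapply(1:80, function(r) {
    sim <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 16,
                                              nGroups = 1,
                                              nAutosomalSites = 60,
                                              groupAlleleFreqDivergence = 0,
                                              missingRate = 0, sexRatio = 0,
                                              seed = 4300 + r))
    gm <- extractBiallelicSnps(sim$genotypes)
    lab <- sample(rep(c("A", "B"), each = 8))
    res <- phiSt(gm, setNames(lab, colnames(gm)))
    sa <- res$components[["sigmaAmong"]]
    sa / (sa + res$components[["sigmaWithin"]])   # unclamped ratio
  }, 0)
  expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)))
  # relabeling the two populations leaves the statistic unchanged
  sim <- simulateGenotypeMatrix(StudyDesign(nSamplesPerGroup = 16,
                                            nGroups = 1,
                                            nAutosomalSites = 100,
                                            groupAlleleFreqDivergence = 0,
                                            missingRate = 0, sexRatio = 0,
                                            seed = 44))
  gm <- extractBiallelicSnps(sim$genotypes)
  lab <- rep(c("A", "B"), 8)
  f <- phiSt(gm, setNames(lab, colnames(gm)))
  g <- phiSt(gm, setNames(c(B = "B", A = "A")[lab], colnames(gm)),
             pair = c("B", "A"))
  expect_equal(f$composite, g$composite, tolerance = 1e-12)
})

test_that("haplotype census counts, distances and sharing", {
  seqs <- c("aaa", "aat", "aat", "aaa", "aaa")
  m <- ape::as.DNAbin(t(vapply(strsplit(seqs, ""), identity, character(3))))
  cen <- haplotypeCensus(m, c("sp1", "sp1", "sp1", "sp2", "sp2"))
  expect_equal(unname(cen@counts[c("sp1", "sp2")]), c(2L, 1L))
  expect_equal(unname(cen@dist["H1", "H2"]), 1)
  expect_equal(unique(cen@shared$haplotype), "H1")  # aaa in both species
  # identical sequences collapse to one haplotype
  one <- haplotypeCensus(ape::as.DNAbin(matrix(rep(c("a", "c"), 5), 5, 2,
                                               byrow = TRUE)),
                         rep("sp1", 5))
  expect_equal(unname(one@counts), 1L)
  # disjoint haplotype sets: no sharing (reciprocal monophyly proxy)
  seqs2 <- c("aaa", "aag", "ttt", "ttc")
  m2 <- ape::as.DNAbin(t(vapply(strsplit(seqs2, ""), identity,
                                character(3))))
  cen2 <- haplotypeCensus(m2, c("sp1", "sp1", "sp2", "sp2"))
  expect_equal(nrow(cen2@shared), 0L)
  expect_error(haplotypeCensus(as.list(m2)[c(1, 2)], "sp1"),
               "label|length")
})
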