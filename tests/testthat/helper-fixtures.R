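# in-code fixtures shared across test files

# build a GenotypeMatrix directly from compact per-site specifications:
# gtStr is a sites x samples character matrix like "0/1"; depths a parallel
# list of c(refDepth, altDepth) or a single number used for both alleles
makeGm <- function(gtStr, qual = NULL, chrom = NULL, pos = NULL,
                   adRef = NULL, adAlt = NULL, sampleIds = NULL,
                   group = NULL) {
  gtStr <- as.matrix(gtStr)
  nS <- nrow(gtStr); nI <- ncol(gtStr)
  if (is.null(qual)) qual <- rep(60, nS)
  if (is.null(chrom)) chrom <- rep("chr1", nS)
  if (is.null(pos)) pos <- seq_len(nS)
  if (is.null(adRef)) adRef <- matrix(20, nS, nI)
  if (is.null(adAlt)) adAlt <- matrix(20, nS, nI)
  if (is.null(sampleIds)) sampleIds <- sprintf("s%02d", seq_len(nI))
  part <- function(i) {
    v <- suppressWarnings(
      vapply(strsplit(gtStr, "[/|]"), function(x) x[i], ""))
    m <- matrix(as.integer(ifelse(v == ".", NA, v)), nS, nI)
    m
  }
  gt1 <- part(1); gt2 <- part(2)
  ad <- array(NA_real_, c(nS, nI, 3L))
  called <- !is.na(gt1)
  a <- adRef; a[!called] <- NA; ad[, , 1] <- a
  a <- adAlt; a[!called] <- NA; ad[, , 2] <- a
  GenotypeMatrix(chrom, pos, ref = rep("A", nS), alt = rep("T", nS),
                 qual = qual, gt1 = gt1, gt2 = gt2, ad = ad,
                 sampleIds = sampleIds, group = group)
}

# write a small plain-text VCF from the same site specification
writeToyVcf <- function(path, gtAd, chrom = NULL, pos = NULL, qual = NULL,
                        alt = NULL, samples = NULL) {
  # gtAd: sites x samples character matrix of "GT:AD" entries
  gtAd <- as.matrix(gtAd)
  nS <- nrow(gtAd); nI <- ncol(gtAd)
  if (is.null(chrom)) chrom <- rep("chr1", nS)
  if (is.null(pos)) pos <- seq_len(nS)
  if (is.null(qual)) qual <- rep(60, nS)
  if (is.null(alt)) alt <- rep("T", nS)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nI))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nS), function(s)
    paste(c(chrom[s], pos[s], ".", "A", alt[s], qual[s], "PASS", ".",
            "GT:AD", gtAd[s, ]), collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

# exact HWE p-value by direct factorial enumeration (independent oracle:
# conditional probability of each heterozygote count computed from the
# textbook closed form with factorial(), exact integers for small n)
hweOracleP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(NA_real_)
  nr <- min(nA, na)
  hs <- seq(nr %% 2, nr, by = 2)
  pr <- sapply(hs, function(h) {
    n1 <- (nr - h) / 2
    n2 <- (2 * n - nr - h) / 2
    2^h * factorial(n) / (factorial(n1) * factorial(h) * factorial(n2)) *
      factorial(nr) * factorial(2 * n - nr) / factorial(2 * n)
  })
  pObs <- pr[match(nAa, hs)]
  sum(pr[pr <= pObs * (1 + 1e-12)])
}

# brute-force AMOVA Phi_ST oracle from an explicit squared-distance matrix
phiOracle <- function(D, pops) {
  pops <- as.factor(pops)
  N <- length(pops)
  P <- nlevels(pops)
  ssT <- sum(D[lower.tri(D)]) / N
  ssW <- 0
  nPer <- table(pops)
  for (lev in levels(pops)) {
    i <- which(pops == lev)
    sub <- D[i, i, drop = FALSE]
    ssW <- ssW + sum(sub[lower.tri(sub)]) / length(i)
  }
  ssA <- ssT - ssW
  sigW <- ssW / (N - P)
  n0 <- (N - sum(nPer^2) / N) / (P - 1)
  sigA <- (ssA / (P - 1) - sigW) / n0
  sigA / (sigA + sigW)
}

# per-site 0/1 squared-distance matrix between haploid allele draws
alleleDistMatrix <- function(alleles) {
  outer(alleles, alleles, function(a, b) as.numeric(a != b))
}

# crafted 50-site, 60-sample VCF exercising every retention rule, with
# hand-derived expected outcomes:
#   sites  1-28 clean biallelic in per-population HWE          -> retained
#   sites 29-30 total heterozygote deficit (15/0/15 per pop)   -> retained,
#               flagged by the exact HWE screen at alpha 1e-6
#               (p = 1.3e-9 in each population)
#   sites 31-33 lone alt carrier supported by a 4x allele      -> genotype
#               invalidated, site monomorphic -> removed
#   sites 34-35 one 4x heterozygote among real polymorphism    -> genotype
#               invalidated, site retained (59/60 = 98% presence)
#   sites 36-40 site PHRED 25 (< 30)                           -> removed
#   sites 41-44 15 of 60 genotypes missing (75% presence)      -> removed
#   sites 45-47 tri-allelic                                    -> removed
#   sites 48-50 monomorphic reference                          -> removed
# survivors: 28 + 2 + 2 = 32; HWE flags: 2
makeFilterBenchVcf <- function(path) {
  nS <- 60
  hetOk <- "0/1:20,20"; homR <- "0/0:40,0"; homA <- "1/1:0,40"
  cleanPop <- c(rep(homR, 10), rep(hetOk, 15), rep(homA, 5))
  clean <- c(cleanPop, cleanPop)
  hweBad <- rep(c(rep(homR, 15), rep(homA, 15)), 2)
  loneLowHet <- c("0/1:4,11", rep(homR, nS - 1))
  lowHetPoly <- c("0/1:4,11", rep(homR, 29), cleanPop)
  missing15 <- c(rep("./.:0,0", 15), clean[16:60])
  triall <- c(rep(homR, 20), rep(hetOk, 20), rep("0/2:20,0,20", 20))
  mono <- rep(homR, nS)
  gt <- rbind(
    matrix(rep(clean, 28), 28, nS, byrow = TRUE),
    matrix(rep(hweBad, 2), 2, nS, byrow = TRUE),
    matrix(rep(loneLowHet, 3), 3, nS, byrow = TRUE),
    matrix(rep(lowHetPoly, 2), 2, nS, byrow = TRUE),
    matrix(rep(clean, 5), 5, nS, byrow = TRUE),
    matrix(rep(missing15, 4), 4, nS, byrow = TRUE),
    matrix(rep(triall, 3), 3, nS, byrow = TRUE),
    matrix(rep(mono, 3), 3, nS, byrow = TRUE))
  qual <- rep(60, 50); qual[36:40] <- 25
  alt <- rep("T", 50); alt[45:47] <- "T,G"
  writeToyVcf(path, gt, qual = qual, alt = alt,
              samples = sprintf("s%02d", 1:60))
  list(path = path,
       populations = setNames(rep(c("A", "B"), each = 30),
                              sprintf("s%02d", 1:60)),
       expectedSurvivors = 32L,
       expectedHweFlags = 2L,
       hweSites = c("chr1:29", "chr1:30"))
}
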