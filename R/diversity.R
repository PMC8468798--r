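## per-site components of average pairwise difference among called alleles:
## x alternate copies among m called -> x (m - x) differing pairs of
## choose(m, 2); sites with fewer than 2 called alleles contribute NA
.sitePi <- function(x, m) ifelse(m >= 2, x * (m - x) / choose(m, 2),
                                 NA_real_)

.alleleCounts <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- gm[, samples]
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  called <- !is.na(g1) & !is.na(g2)
  list(m = 2 * rowSums(called),
       x = rowSums((g1 == 1L) * called, na.rm = TRUE) +
         rowSums((g2 == 1L) * called, na.rm = TRUE))
}

#' @describeIn nucleotideDiversity per-site allele counts aggregated per
#'   chromosome (each chromosome a locus); pi is per callable site in the
#'   matrix.  The `concatenated` row weights loci by callable length.
#' @param populations optional sample subset/grouping: a character vector
#'   of sample ids to restrict to.
setMethod("nucleotideDiversity", "GenotypeMatrix",
  function(x, populations = NULL, ...) {
    ac <- .alleleCounts(x, populations)
    sp <- .sitePi(ac$x, ac$m)
    chrom <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(x)))
    callable <- !is.na(sp)
    if (!any(callable)) {
      return(data.frame(locus = "concatenated", pi = NA_real_, L = 0))
    }
    agg <- tapply(sp[callable], chrom[callable], sum)
    L <- tapply(rep(1, sum(callable)), chrom[callable], sum)
    out <- data.frame(locus = names(agg), pi = as.numeric(agg / L),
                      L = as.numeric(L), row.names = NULL)
    rbind(out, data.frame(locus = "concatenated",
                          pi = sum(sp[callable]) / sum(callable),
                          L = sum(callable)))
  })

#' @describeIn nucleotideDiversity mean over all sequence pairs of the
#'   proportion of differing sites, with pairwise deletion of missing or
#'   ambiguous positions (via `ape::dist.dna`).
setMethod("nucleotideDiversity", "DNAbin", function(x, ...) {
  if (is.list(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 sequences")
  d <- ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE)
  data.frame(locus = "concatenated", pi = mean(d, na.rm = TRUE),
             L = ncol(x))
})

## AMOVA variance components from per-population pairwise-difference sums
## of squares; d2W[p] = sum of squared distances among pop p, d2T = over all
.amovaComponents <- function(ssW, nPer, ssT) {
  N <- sum(nPer)
  P <- length(nPer)
  ssA <- ssT - sum(ssW)
  dfA <- P - 1
  dfW <- N - P
  sigW <- sum(ssW) / dfW
  n0 <- (N - sum(nPer^2) / N) / dfA
  sigA <- (ssA / dfA - sigW) / n0
  list(sigmaAmong = sigA, sigmaWithin = sigW)
}

## Phi_ST from a matrix of squared pairwise distances and a population factor
.phiFromDist <- function(D, pops) {
  pops <- as.factor(pops)
  N <- length(pops)
  idx <- split(seq_len(N), pops)
  if (any(lengths(idx) < 2L))
    stop("each population needs at least 2 sampled sequences")
  ssT <- sum(D[lower.tri(D)]) / N
  ssW <- vapply(idx, function(i) {
    sub <- D[i, i, drop = FALSE]
    sum(sub[lower.tri(sub)]) / length(i)
  }, 0)
  cmp <- .amovaComponents(ssW, lengths(idx), ssT)
  tot <- cmp$sigmaAmong + cmp$sigmaWithin
  phi <- if (tot > 0) cmp$sigmaAmong / tot else 0
  c(phi = phi, sigmaAmong = cmp$sigmaAmong, sigmaWithin = cmp$sigmaWithin)
}

## per-site AMOVA components for two populations from allele counts,
## treating the two allele copies of each diploid as independent haploid
## draws (squared distance between copies is 0/1)
.phiSiteComponents <- function(x1, m1, x2, m2) {
  ok <- m1 >= 2 & m2 >= 2
  nS <- length(x1)
  sigA <- sigW <- rep(NA_real_, nS)
  for (s in which(ok)) {
    nPer <- c(m1[s], m2[s])
    ssW <- c(x1[s] * (m1[s] - x1[s]) / m1[s],
             x2[s] * (m2[s] - x2[s]) / m2[s])
    xt <- x1[s] + x2[s]; mt <- m1[s] + m2[s]
    ssT <- xt * (mt - xt) / mt
    cmp <- .amovaComponents(ssW, nPer, ssT)
    sigA[s] <- cmp$sigmaAmong
    sigW[s] <- cmp$sigmaWithin
  }
  data.frame(sigmaAmong = sigA, sigmaWithin = sigW)
}

#' @describeIn phiSt per-site AMOVA on allele counts, aggregated per
#'   chromosome and overall.  The composite is the ratio of summed
#'   variance components (equivalent to AMOVA on the concatenated data),
#'   with a negative among-population sum clamped to zero; per-site and
#'   per-locus raw values are preserved unclamped.
#' @param pair length-2 character vector naming the two populations to
#'   compare (defaults to the first two levels).
setMethod("phiSt", signature(x = "GenotypeMatrix"),
  function(x, populations, pair = NULL, ...) {
    if (!is.null(names(populations))) populations <- populations[colnames(x)]
    populations <- as.character(populations)
    if (length(populations) != ncol(x))
      stop("populations must map every sample")
    if (is.null(pair)) pair <- unique(populations)[1:2]
    s1 <- colnames(x)[populations == pair[1]]
    s2 <- colnames(x)[populations == pair[2]]
    if (length(s1) < 1L || length(s2) < 1L)
      stop("insufficient data: both populations need sampled genotypes")
    a1 <- .alleleCounts(x, s1)
    a2 <- .alleleCounts(x, s2)
    if (max(a1$m) < 2 || max(a2$m) < 2)
      stop("insufficient data: both populations need >= 2 sequences")
    cmp <- .phiSiteComponents(a1$x, a1$m, a2$x, a2$m)
    tot <- cmp$sigmaAmong + cmp$sigmaWithin
    perSite <- ifelse(!is.na(tot) & tot > 0, cmp$sigmaAmong / tot,
                      ifelse(is.na(tot), NA_real_, 0))
    chrom <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(x)))
    ok <- !is.na(tot)
    aggA <- tapply(cmp$sigmaAmong[ok], chrom[ok], sum)
    aggW <- tapply(cmp$sigmaWithin[ok], chrom[ok], sum)
    perLocus <- data.frame(locus = names(aggA),
                           phiSt = as.numeric(aggA / (aggA + aggW)),
                           row.names = NULL)
    sumA <- sum(cmp$sigmaAmong[ok]); sumW <- sum(cmp$sigmaWithin[ok])
    composite <- max(sumA, 0) / (max(sumA, 0) + sumW)
    list(pair = pair, composite = composite, perLocus = perLocus,
         perSite = data.frame(site = rownames(x), phiSt = perSite,
                              sigmaAmong = cmp$sigmaAmong,
                              sigmaWithin = cmp$sigmaWithin),
         components = c(sigmaAmong = sumA, sigmaWithin = sumW))
  })

#' @describeIn phiSt AMOVA on pairwise mutation-count distances between
#'   aligned sequences (haplotype mode; `ape::dist.dna` model "N" with
#'   pairwise deletion).
setMethod("phiSt", signature(x = "DNAbin"),
  function(x, populations, ...) {
    if (is.list(x)) x <- as.matrix(x)
    pops <- as.character(populations)
    if (length(pops) != nrow(x)) stop("populations must map every sequence")
    if (any(table(pops) < 2L))
      stop("insufficient data: each population needs >= 2 sequences")
    D <- as.matrix(ape::dist.dna(x, model = "N", pairwise.deletion = TRUE))
    res <- .phiFromDist(D, pops)
    list(pair = unique(pops), composite = max(res[["phi"]], 0),
         raw = res[["phi"]],
         components = res[c("sigmaAmong", "sigmaWithin")])
  })

#' Census of haplotypes in an aligned set of sequences
#'
#' Collapses identical sequences into haplotypes (exact character match,
#' case-insensitive), counts them per species, computes pairwise
#' mutation-count distances between the distinct haplotypes (ambiguous or
#' missing positions excluded pairwise) and reports haplotypes observed in
#' more than one species.
#'
#' @param alignment an `ape::DNAbin` matrix of equal-length aligned
#'   sequences.
#' @param species character vector of species labels, one per sequence.
#' @return a [HaplotypeCensus-class].
#' @export
haplotypeCensus <- function(alignment, species) {
  if (is.list(alignment)) {
    if (length(unique(lengths(alignment))) != 1L)
      stop("sequences must be aligned to equal length")
    alignment <- as.matrix(alignment)
  }
  species <- as.character(species)
  if (length(species) != nrow(alignment))
    stop("species must label every sequence")
  chars <- toupper(apply(as.character(alignment), 1L, paste, collapse = ""))
  hap <- match(chars, unique(chars))
  hapNames <- paste0("H", seq_along(unique(chars)))
  freq <- as.data.frame(table(haplotype = hapNames[hap], species = species),
                        stringsAsFactors = FALSE)
  freq <- freq[freq$Freq > 0L, ]
  names(freq)[3] <- "count"
  counts <- vapply(split(hap, species), function(h) length(unique(h)), 0L)
  first <- match(unique(chars), chars)
  hapAln <- alignment[first, , drop = FALSE]
  rownames(hapAln) <- hapNames
  D <- as.matrix(ape::dist.dna(hapAln, model = "N",
                               pairwise.deletion = TRUE))
  bySpecies <- table(hapNames[hap], species)
  sharedIdx <- rownames(bySpecies)[rowSums(bySpecies > 0L) > 1L]
  shared <- freq[freq$haplotype %in% sharedIdx, , drop = FALSE]
  new("HaplotypeCensus", counts = setNames(as.integer(counts),
                                           names(counts)),
      freq = freq, dist = D, shared = shared)
}

setMethod("show", "HaplotypeCensus", function(object) {
  cat("HaplotypeCensus:",
      sum(tapply(object@freq$count, object@freq$haplotype, sum) > 0),
      "distinct haplotypes\n")
  for (s in names(object@counts))
    cat(sprintf("  %s: %d haplotype(s)\n", s, object@counts[[s]]))
  cat(" ", nrow(object@shared), "haplotype-species sharing record(s)\n")
})
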