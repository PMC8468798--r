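#' Construct a GenotypeMatrix
#'
#' Low-level constructor used by the VCF reader and the simulator.  Sites
#' are sorted by chromosome and position; duplicated positions within a
#' chromosome are an error.
#'
#' @param chrom character vector of chromosome ids.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt,alt2 allele strings (`alt2` `NA` or "" for biallelic
#'   sites).
#' @param qual numeric site PHRED scores.
#' @param gt1,gt2 integer matrices (sites x samples) of allele indices.
#' @param ad numeric array sites x samples x 3 of per-allele depths.
#' @param sampleIds character vector of sample names.
#' @param group optional character vector of group labels per sample.
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(chrom, pos, ref, alt, qual, gt1, gt2, ad,
                           sampleIds, alt2 = NA_character_, group = NULL) {
  if (any(nchar(ref) == 0L)) stop("alleles must be non-empty")
  o <- order(chrom, pos)
  if (anyDuplicated(paste(chrom, pos)))
    stop("positions must be strictly increasing within a chromosome")
  alt2 <- rep_len(alt2, length(chrom))
  gr <- GenomicRanges::GRanges(chrom[o], IRanges::IRanges(pos[o], width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = ref[o], alt = alt[o], alt2 = alt2[o], qual = qual[o])
  cd <- S4Vectors::DataFrame(sampleId = sampleIds,
                             row.names = sampleIds)
  if (!is.null(group)) cd$group <- group
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT1 = gt1[o, , drop = FALSE],
                  GT2 = gt2[o, , drop = FALSE],
                  AD = ad[o, , , drop = FALSE]),
    rowRanges = gr, colData = cd)
  rownames(se) <- paste0(chrom[o], ":", pos[o])
  colnames(se) <- sampleIds
  new("GenotypeMatrix", se)
}

setMethod("show", "GenotypeMatrix", function(object) {
  ncall <- sum(!is.na(SummarizedExperiment::assay(object, "GT1")))
  cat(sprintf(
    "GenotypeMatrix: %d sites x %d samples (%.1f%% genotypes called)\n",
    nrow(object), ncol(object),
    100 * ncall / max(1L, nrow(object) * ncol(object))))
  cat("  chromosomes:",
      paste(unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object)))), collapse = " "), "\n")
})

.parseAd <- function(adStr) {
  # "3,2" / "3,2,0" / NA -> numeric length-3 (NA padded)
  out <- matrix(NA_real_, length(adStr), 3L)
  ok <- !is.na(adStr) & adStr != "." & adStr != ""
  if (any(ok)) {
    parts <- strsplit(adStr[ok], ",", fixed = TRUE)
    for (i in seq_along(parts)) {
      v <- suppressWarnings(as.numeric(parts[[i]]))
      out[which(ok)[i], seq_len(min(3L, length(v)))] <-
        v[seq_len(min(3L, length(v)))]
    }
  }
  out
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Loads GT (required) and AD (optional) fields of a VCF 4.x file via
#' `vcfR`.  Missing genotypes (`./.`) are preserved as missing; positions
#' stay 1-based.  Sites with more than two ALT alleles are rejected.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!"GT" %in% fmt) stop("VCF has no GT field: ", path)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-variant VCF
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  altRaw <- fix[, "ALT"]
  altRaw[is.na(altRaw)] <- ""
  altSplit <- strsplit(altRaw, ",", fixed = TRUE)
  nalt <- lengths(altSplit)
  if (any(nalt > 2L))
    stop("sites with more than two ALT alleles are not supported (line ",
         which(nalt > 2L)[1], ")")
  alt <- vapply(altSplit, function(a) if (length(a) >= 1L) a[1] else "", "")
  alt2 <- vapply(altSplit, function(a)
    if (length(a) >= 2L) a[2] else NA_character_, "")
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gtStr <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gtStr)
  splitAllele <- function(which) {
    m <- matrix(NA_integer_, nrow(gtStr), ncol(gtStr))
    ok <- !is.na(gtStr)
    toks <- strsplit(gtStr[ok], "[/|]")
    bad <- lengths(toks) != 2L
    if (any(bad))
      stop("malformed genotype record at matrix entry ", which(ok)[bad][1])
    vals <- vapply(toks, `[`, "", which)
    vals[vals == "."] <- NA_character_
    m[ok] <- suppressWarnings(as.integer(vals))
    m
  }
  gt1 <- splitAllele(1L)
  gt2 <- splitAllele(2L)
  half <- is.na(gt1) != is.na(gt2)
  if (any(half)) { gt1[half] <- NA_integer_; gt2[half] <- NA_integer_ }
  ad <- array(NA_real_, c(nrow(gtStr), ncol(gtStr), 3L))
  if ("AD" %in% fmt) {
    adStr <- vcfR::extract.gt(v, element = "AD")
    flat <- .parseAd(as.vector(adStr))
    ad <- array(flat, c(nrow(gtStr), ncol(gtStr), 3L))
  }
  GenotypeMatrix(chrom, pos, ref, alt, qual, gt1, gt2, ad, samples,
                 alt2 = alt2)
}

#' Write a GenotypeMatrix as VCF 4.2
#'
#' Emits GT and AD fields through `vcfR::write.vcf` (output is gzipped, so
#' `path` should end in `.vcf.gz`).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  ad <- SummarizedExperiment::assay(gm, "AD")
  rd <- SummarizedExperiment::rowData(gm)
  rr <- SummarizedExperiment::rowRanges(gm)
  nS <- nrow(gm)
  alt <- ifelse(is.na(rd$alt2) | rd$alt2 == "", rd$alt,
                paste(rd$alt, rd$alt2, sep = ","))
  fix <- cbind(CHROM = as.character(GenomicRanges::seqnames(rr)),
               POS = as.character(GenomicRanges::start(rr)),
               ID = rep(".", nS), REF = rd$ref, ALT = alt,
               QUAL = format(rd$qual, trim = TRUE), FILTER = rep("PASS", nS),
               INFO = rep(".", nS))
  gtCell <- function(a1, a2, d1, d2) {
    gt <- ifelse(is.na(a1), "./.", paste0(a1, "/", a2))
    d1 <- ifelse(is.na(d1), 0, d1)
    d2 <- ifelse(is.na(d2), 0, d2)
    paste0(gt, ":", round(d1), ",", round(d2))
  }
  gt <- matrix("", nS, ncol(gm) + 1L)
  gt[, 1L] <- "GT:AD"
  for (s in seq_len(ncol(gm)))
    gt[, s + 1L] <- gtCell(g1[, s], g2[, s], ad[, s, 1L], ad[, s, 2L])
  colnames(gt) <- c("FORMAT", colnames(gm))
  out <- new("vcfR",
             meta = c("##fileformat=VCFv4.2",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"),
             fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

.newReport <- function() {
  data.frame(filter = character(), unit = character(),
             input = numeric(), removed = numeric(), retained = numeric(),
             stringsAsFactors = FALSE)
}

.addReport <- function(rep, filter, unit, input, removed) {
  rbind(rep, data.frame(filter = filter, unit = unit, input = input,
                        removed = removed, retained = input - removed,
                        stringsAsFactors = FALSE))
}

#' Apply site-retention filters to a genotype matrix
#'
#' A genotype call is invalidated (set missing) when any of its called
#' alleles is covered by fewer than `minAlleleDepth` reads or when the site
#' PHRED quality is below `minPhred`; a site is then dropped when the
#' fraction of alleles still present across samples falls below
#' `minPresence`.  Defaults mirror a 5x-per-allele / PHRED 30 / 80%-presence
#' regime.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param minAlleleDepth minimum reads supporting each called allele.
#' @param minPhred minimum site PHRED quality.
#' @param minPresence minimum fraction of alleles present at a retained
#'   site, in (0, 1].
#' @return a list with elements `genotypes` (the filtered
#'   [GenotypeMatrix-class]) and `report` (a data.frame tallying each rule,
#'   in application order).
#' @export
filterSites <- function(gm, minAlleleDepth = 5, minPhred = 30,
                        minPresence = 0.8) {
  if (nrow(gm) == 0L) stop("empty genotype matrix")
  if (minAlleleDepth < 0 || minPhred < 0 || minPresence <= 0 ||
      minPresence > 1)
    stop("filter thresholds outside valid ranges")
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  ad <- SummarizedExperiment::assay(gm, "AD")
  qual <- SummarizedExperiment::rowData(gm)$qual
  called <- !is.na(g1)
  nCalled0 <- sum(called)
  depthOf <- function(gt) {
    # depth supporting allele index gt (0/1/2) at each cell
    d <- matrix(NA_real_, nrow(g1), ncol(g1))
    for (a in 0:2) {
      sel <- !is.na(gt) & gt == a
      if (any(sel)) d[sel] <- ad[, , a + 1L][sel]
    }
    d
  }
  d1 <- depthOf(g1)
  d2 <- depthOf(g2)
  lowDepth <- called & (is.na(d1) | d1 < minAlleleDepth |
                          is.na(d2) | d2 < minAlleleDepth)
  report <- .newReport()
  report <- .addReport(report, "allele_depth", "genotypes", nCalled0,
                       sum(lowDepth))
  g1[lowDepth] <- NA_integer_
  g2[lowDepth] <- NA_integer_
  lowQ <- is.na(qual) | qual < minPhred
  stillCalled <- !is.na(g1)
  report <- .addReport(report, "site_quality", "genotypes",
                       sum(stillCalled), sum(stillCalled[lowQ, , drop = FALSE]))
  g1[lowQ, ] <- NA_integer_
  g2[lowQ, ] <- NA_integer_
  presence <- rowSums(!is.na(g1)) / ncol(gm)
  keep <- presence >= minPresence
  report <- .addReport(report, "presence", "sites", nrow(gm), sum(!keep))
  adx <- SummarizedExperiment::assay(gm, "AD")
  for (a in 1:3) { sl <- adx[, , a]; sl[is.na(g1)] <- NA_real_; adx[, , a] <- sl }
  out <- gm
  SummarizedExperiment::assay(out, "GT1") <- g1
  SummarizedExperiment::assay(out, "GT2") <- g2
  SummarizedExperiment::assay(out, "AD") <- adx
  out <- out[keep, ]
  list(genotypes = out, report = report)
}

#' Exact Hardy-Weinberg screen, population-aware
#'
#' Runs the exact conditional Hardy-Weinberg test ([hweExactP()]) per site
#' within each population separately (never pooled, so that population
#' structure does not masquerade as disequilibrium) and flags sites that
#' deviate at `p < alpha` in at least one population.  Flagged sites are
#' reported, not removed.
#'
#' @param gm a [GenotypeMatrix-class] (biallelic sites tested; others
#'   skipped).
#' @param populations named character/factor mapping every sample to one
#'   population, or a vector in column order.
#' @param alpha flagging threshold on the exact p-value.
#' @return list with `flagged` (logical per site), `pvalues` (site x
#'   population matrix) and `report`.
#' @export
hweScreen <- function(gm, populations, alpha = 1e-6) {
  if (!is.null(names(populations)))
    populations <- populations[colnames(gm)]
  populations <- as.character(populations)
  if (length(populations) != ncol(gm) || anyNA(populations))
    stop("every sample must be assigned to exactly one population")
  pops <- unique(populations)
  if (any(table(populations) < 1L)) stop("empty population")
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  pv <- matrix(NA_real_, nrow(gm), length(pops),
               dimnames = list(rownames(gm), pops))
  for (p in pops) {
    sel <- populations == p
    a1 <- g1[, sel, drop = FALSE]
    a2 <- g2[, sel, drop = FALSE]
    called <- !is.na(a1) & a1 <= 1L & a2 <= 1L
    nAA <- rowSums(called & a1 == 0L & a2 == 0L, na.rm = TRUE)
    nAa <- rowSums(called & (a1 + a2 == 1L), na.rm = TRUE)
    naa <- rowSums(called & a1 == 1L & a2 == 1L, na.rm = TRUE)
    pv[, p] <- vapply(seq_len(nrow(gm)), function(s)
      hweExactP(nAA[s], nAa[s], naa[s]), 0)
  }
  flagged <- apply(pv < alpha, 1L, any, na.rm = TRUE)
  report <- .addReport(.newReport(), "hwe_flag", "sites", nrow(gm),
                       sum(flagged))
  list(flagged = flagged, pvalues = pv, report = report)
}

#' Retain only biallelic segregating sites
#'
#' Keeps sites at which exactly two alleles are observed among called
#' genotypes, each at least once.  Monomorphic (including sites made
#' monomorphic by genotype invalidation) and multi-allelic sites are
#' removed.  Singletons are retained; masking of rare classes is an
#' SFS-level decision.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return the reduced [GenotypeMatrix-class].
#' @export
extractBiallelicSnps <- function(gm) {
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  nAllele <- function(a) rowSums(!is.na(g1) & g1 == a, na.rm = TRUE) +
    rowSums(!is.na(g2) & g2 == a, na.rm = TRUE)
  c0 <- nAllele(0L); c1 <- nAllele(1L); c2 <- nAllele(2L)
  nObs <- (c0 > 0L) + (c1 > 0L) + (c2 > 0L)
  gm[nObs == 2L & c2 == 0L, ]
}
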