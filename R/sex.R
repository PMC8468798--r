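## 1D two-cluster split minimizing within-cluster sum of squares (Otsu);
## returns NA when the data do not support two separated clusters
.upperClusterCentre <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4L) return(stats::median(x))
  wss <- vapply(seq_len(n - 1L), function(k) {
    a <- x[seq_len(k)]; b <- x[-seq_len(k)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, 0)
  k <- which.min(wss)
  lower <- x[seq_len(k)]; upper <- x[-seq_len(k)]
  # treat as a single cluster (e.g. an all-male cohort) when the gap
  # between the putative modes is small relative to their level
  if (mean(upper) - mean(lower) < 0.2 * mean(upper)) return(stats::median(x))
  stats::median(upper)
}

#' Assign genetic sex from Z-to-autosome depth and heterozygosity
#'
#' In a ZW system, males (ZZ) carry two Z copies and females (ZW) one, so
#' Z-linked markers in females are recovered at about half the autosomal
#' sequencing depth and appear homozygous.  Per sample the depth ratio
#' (mean Z depth over mean autosomal depth) is normalized by the cohort's
#' male mode (the upper mode of the ratio distribution), cancelling
#' between-library depth differences.  A sample is called female only when
#' both lines of evidence agree - normalized ratio at most
#' `femaleRatioMax` and Z-to-autosome heterozygosity ratio at most
#' `hetRatioMaxForFemale`; depth alone suffices for a male call
#' (normalized ratio at least `maleRatioMin`).  Everything else, including
#' samples with undefined ratios, is left unassigned with its evidence
#' reported.
#'
#' @param gm a [GenotypeMatrix-class] with depth data.
#' @param zChromosomes character vector of Z-chromosome names.
#' @param femaleRatioMax upper normalized-ratio bound for a female call.
#' @param maleRatioMin lower normalized-ratio bound for a male call.
#' @param hetRatioMaxForFemale upper bound on z-het / autosomal-het for a
#'   female call.
#' @return data.frame with one row per sample: `sampleId`,
#'   `zAutosomeDepthRatio` (normalized), `zHeterozygosity`,
#'   `autosomalHeterozygosity`, `call`.
#' @export
assignSex <- function(gm, zChromosomes = "chrZ", femaleRatioMax = 0.65,
                      maleRatioMin = 0.85, hetRatioMaxForFemale = 0.1) {
  chrom <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(gm)))
  isZ <- chrom %in% zChromosomes
  if (!any(isZ)) stop("no sites on the requested Z chromosome(s)")
  if (all(isZ)) stop("no autosomal sites with depth data")
  ad <- SummarizedExperiment::assay(gm, "AD")
  depth <- ad[, , 1L]
  depth[is.na(depth)] <- 0
  d2 <- ad[, , 2L]; d2[is.na(d2)] <- 0
  depth <- depth + d2
  called <- !is.na(SummarizedExperiment::assay(gm, "GT1"))
  depth[!called] <- NA  # depth evidence only where a call was made
  g1 <- SummarizedExperiment::assay(gm, "GT1")
  g2 <- SummarizedExperiment::assay(gm, "GT2")
  het <- g1 != g2
  zDepth <- colMeans(depth[isZ, , drop = FALSE], na.rm = TRUE)
  aDepth <- colMeans(depth[!isZ, , drop = FALSE], na.rm = TRUE)
  zHet <- colMeans(het[isZ, , drop = FALSE], na.rm = TRUE)
  aHet <- colMeans(het[!isZ, , drop = FALSE], na.rm = TRUE)
  raw <- ifelse(aDepth > 0, zDepth / aDepth, NA_real_)
  maleMode <- .upperClusterCentre(raw)
  ratio <- raw / maleMode
  hetRatio <- ifelse(aHet > 0, zHet / aHet, ifelse(zHet == 0, 0, Inf))
  call <- rep("unassigned", ncol(gm))
  call[!is.na(ratio) & ratio <= femaleRatioMax &
         hetRatio <= hetRatioMaxForFemale] <- "female"
  call[!is.na(ratio) & ratio >= maleRatioMin] <- "male"
  data.frame(sampleId = colnames(gm), zAutosomeDepthRatio = unname(ratio),
             zHeterozygosity = unname(zHet),
             autosomalHeterozygosity = unname(aHet), call = call,
             stringsAsFactors = FALSE)
}
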