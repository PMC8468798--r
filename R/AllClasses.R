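#' @useDynLib coalstep, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats optim rbinom rnbinom rpois runif rnorm setNames
#'   dhyper qnorm median sd
#' @importFrom utils write.table read.table packageVersion capture.output
#' @importFrom SummarizedExperiment rowData assay assayNames rowRanges
#'   colData SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom vcfR vcfR
NULL

setOldClass("DNAbin")

#' One-dimensional site-frequency spectrum
#'
#' Counts of variant sites indexed by the number of sampled allele copies
#' (0..n) carrying the alternate (unfolded) or minor (folded) allele, with a
#' per-entry mask and the total callable sequence length used for
#' theta scaling.
#'
#' @slot entries numeric vector of length `n + 1`; entry `i + 1` is the
#'   (possibly fractional, after projection) count of sites with `i` copies.
#' @slot n haploid sample size.
#' @slot folded logical; `TRUE` once [fold()] has been applied.
#' @slot mask logical vector parallel to `entries`; masked entries are kept
#'   for bookkeeping but excluded from likelihoods.
#' @slot L total callable sequence length in base pairs (`NA` if unknown).
#'
#' @seealso [buildSfs1d()], [fold()], [applyMask()], [writeSfs()]
#' @export
setClass("Sfs1D",
  representation(entries = "numeric", n = "integer", folded = "logical",
                 mask = "logical", L = "numeric"),
  prototype(folded = FALSE, L = NA_real_))

setValidity("Sfs1D", function(object) {
  msg <- NULL
  if (length(object@entries) != object@n + 1L)
    msg <- c(msg, "entries must have length n + 1")
  if (length(object@mask) != length(object@entries))
    msg <- c(msg, "mask must be parallel to entries")
  if (any(object@entries < -1e-9, na.rm = TRUE))
    msg <- c(msg, "entries must be non-negative")
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@folded) {
    hi <- seq_len(object@n + 1L) - 1L > floor(object@n / 2)
    if (any(object@entries[hi] != 0))
      msg <- c(msg, "folded spectrum must be zero above floor(n/2)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Joint (two-population) site-frequency spectrum
#'
#' @slot entries numeric matrix of dimension `(n1 + 1) x (n2 + 1)`; cell
#'   `(i + 1, j + 1)` counts sites with `i` copies in population 1 and `j`
#'   in population 2.
#' @slot n1,n2 haploid sample sizes of the two populations.
#' @slot folded logical fold state (minor-allele orientation on total count).
#' @slot mask logical matrix parallel to `entries`.
#' @slot L total callable sequence length in base pairs.
#'
#' @export
setClass("Sfs2D",
  representation(entries = "matrix", n1 = "integer", n2 = "integer",
                 folded = "logical", mask = "matrix", L = "numeric"),
  prototype(folded = FALSE, L = NA_real_))

setValidity("Sfs2D", function(object) {
  msg <- NULL
  if (!all(dim(object@entries) == c(object@n1 + 1L, object@n2 + 1L)))
    msg <- c(msg, "entries must be (n1+1) x (n2+1)")
  if (!all(dim(object@mask) == dim(object@entries)))
    msg <- c(msg, "mask must be parallel to entries")
  if (any(object@entries < -1e-9, na.rm = TRUE))
    msg <- c(msg, "entries must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Stepwise time-interval model of effective population size
#'
#' An ancestral population of relative size `vAnc` (fixed at 1 by
#' normalization) persists for scaled time `tAnc`, after which population
#' size moves through an ordered series of steps, earliest first.  Step `k`
#' has size `v[k]` relative to the ancestral size and lasts `t[k]` units of
#' `2 * N_ANC` generations; the final step ends at the present.
#'
#' @slot v positive numeric vector of relative sizes, earliest first.
#' @slot t non-negative numeric vector of scaled durations, parallel to `v`.
#' @slot vAnc relative ancestral size (1 by convention).
#' @slot tAnc scaled duration of the ancestral period (used only when
#'   rendering a time axis; the coalescent treats the ancestral epoch as
#'   unbounded).
#'
#' @seealso [EpochModel()], [expectedSfsStepwise()], [fitStepwise()]
#' @export
setClass("EpochModel",
  representation(v = "numeric", t = "numeric", vAnc = "numeric",
                 tAnc = "numeric"),
  prototype(vAnc = 1, tAnc = 0))

setValidity("EpochModel", function(object) {
  msg <- NULL
  if (length(object@v) != length(object@t))
    msg <- c(msg, "v and t must have equal length")
  if (any(object@v <= 0) || object@vAnc <= 0)
    msg <- c(msg, "all sizes must be positive")
  if (any(object@t < 0) || object@tAnc < 0)
    msg <- c(msg, "durations must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Result of a composite-likelihood demographic fit
#'
#' @slot modelName model identifier ("stepwise" or a registered pairwise
#'   model name).
#' @slot params named numeric vector of optimized parameters (natural scale).
#' @slot theta analytically profiled population-scaled mutation rate.
#' @slot loglik Poisson composite log-likelihood at the optimum.
#' @slot se named numeric vector of log-scale standard errors (parameters,
#'   then theta).
#' @slot ci matrix with columns `lower`, `upper`; multiplicative 95 percent
#'   (or requested level) intervals on the natural scale.
#' @slot epochModel the rendered [EpochModel-class] (single-population fits)
#'   or `NULL`.
#' @slot nStarts number of optimizer starts.
#' @slot starts data.frame logging every start (start index, log-likelihood,
#'   convergence code).
#' @slot converged logical; at least one start converged.
#' @slot seed integer seed that makes the fit reproducible.
#' @slot obsSummary list identifying the fitted spectrum (sample sizes,
#'   entry checksum) so that fits can be checked for comparability.
#' @slot wideCi logical; `TRUE` when the information matrix was singular and
#'   a pseudo-inverse was used.
#'
#' @export
setClass("FitResult",
  representation(modelName = "character", params = "numeric",
                 theta = "numeric", loglik = "numeric", se = "numeric",
                 ci = "matrix", epochModel = "ANY", nStarts = "integer",
                 starts = "data.frame", converged = "logical",
                 seed = "integer", obsSummary = "list", wideCi = "logical"),
  prototype(epochModel = NULL, wideCi = FALSE))

setValidity("FitResult", function(object) {
  msg <- NULL
  if (length(object@theta) == 1L && !is.na(object@theta) &&
      object@theta <= 0)
    msg <- c(msg, "theta must be positive")
  if (length(object@loglik) == 1L && !is.finite(object@loglik))
    msg <- c(msg, "log-likelihood must be finite at the optimum")
  if (is.null(msg)) TRUE else msg
})

#' Calibration constants for converting scaled parameters
#'
#' Houses the mutation rate, generation time and locus length needed to turn
#' coalescent-scaled quantities (`nu`, `T`, `theta`) into individuals and
#' years via `theta = 4 * N_ANC * mu * L`.
#'
#' @slot muSiteYear mutation rate, substitutions per site per year.
#' @slot G generation time in years.
#' @slot alpha age at sexual maturity in years.
#' @slot survival adult annual survival fraction, in (0, 1).
#' @slot L total locus length in base pairs.
#' @slot anchorTimeYears anchor divergence time in years (optional; used by
#'   [calibrateMu()]).
#' @slot anchorTScaled the same anchor divergence in model time units.
#'
#' @export
setClass("Calibration",
  representation(muSiteYear = "numeric", G = "numeric", alpha = "numeric",
                 survival = "numeric", L = "numeric",
                 anchorTimeYears = "numeric", anchorTScaled = "numeric"))

setValidity("Calibration", function(object) {
  msg <- NULL
  if (!is.na(object@survival) &&
      (object@survival <= 0 || object@survival >= 1))
    msg <- c(msg, "survival must be in (0, 1)")
  for (s in c("muSiteYear", "G", "L")) {
    val <- slot(object, s)
    if (!is.na(val) && val <= 0) msg <- c(msg, paste(s, "must be positive"))
  }
  if (is.null(msg)) TRUE else msg
})

#' Design of a simulated ddRAD-like cohort
#'
#' Parameters of the genotype-matrix emulator: cohort composition, site
#' counts, sequencing depth (median 119 reads, the study-scale default),
#' missingness, sex ratio and between-group allele-frequency divergence.
#'
#' @slot nGroups number of groups (species/populations).
#' @slot nSamplesPerGroup diploid samples per group.
#' @slot nAutosomalSites,nZSites numbers of autosomal and Z-linked sites.
#' @slot medianDepth target per-sample median sequencing depth (reads).
#' @slot missingRate flat per-genotype missingness fraction in [0, 1).
#' @slot sexRatio fraction of females per group.
#' @slot groupAlleleFreqDivergence fraction in [0, 1] mixing a shared
#'   ancestral allele frequency (0) with fixed differences between groups (1).
#' @slot depthOverdispersion negative-binomial size parameter of the depth
#'   model.
#' @slot seed integer seed; identical seeds reproduce identical cohorts.
#'
#' @seealso [simulateGenotypeMatrix()]
#' @export
setClass("StudyDesign",
  representation(nGroups = "integer", nSamplesPerGroup = "integer",
                 nAutosomalSites = "integer", nZSites = "integer",
                 medianDepth = "numeric", missingRate = "numeric",
                 sexRatio = "numeric", groupAlleleFreqDivergence = "numeric",
                 depthOverdispersion = "numeric", seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- NULL
  if (object@nGroups < 1L || object@nSamplesPerGroup < 1L ||
      object@nAutosomalSites < 1L || object@nZSites < 0L)
    msg <- c(msg, "counts must be >= 1 (nZSites may be 0)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (object@sexRatio < 0 || object@sexRatio > 1)
    msg <- c(msg, "sexRatio must be in [0, 1]")
  if (object@groupAlleleFreqDivergence < 0 ||
      object@groupAlleleFreqDivergence > 1)
    msg <- c(msg, "groupAlleleFreqDivergence must be in [0, 1]")
  if (object@medianDepth <= 0) msg <- c(msg, "medianDepth must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Ground truth accompanying a simulated cohort
#'
#' @slot sex character vector of true sexes ("female"/"male"), one per sample.
#' @slot group character vector of group labels, one per sample.
#' @slot alleleFreqs matrix (sites x groups) of generating alternate-allele
#'   frequencies.
#' @slot design the generating [StudyDesign-class].
#'
#' @export
setClass("SimTruth",
  representation(sex = "character", group = "character",
                 alleleFreqs = "matrix", design = "StudyDesign"))

#' Genotype matrix with per-allele depths
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are sites
#' (with 1-based VCF coordinates in `rowRanges`) and whose columns are
#' samples.  Assays: `GT1`/`GT2`, the two integer allele indices of each
#' diploid call (0 = REF, 1 = first ALT, 2 = second ALT, `NA` = missing);
#' `AD`, a three-dimensional array `sites x samples x 3` of per-allele read
#' depths (REF, ALT1, ALT2).  `rowData` carries `ref`, `alt`, `alt2` and
#' `qual` (site PHRED).
#'
#' @seealso [readGenotypeVcf()], [filterSites()], [extractBiallelicSnps()]
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  for (a in c("GT1", "GT2", "AD"))
    if (!a %in% an) msg <- c(msg, paste("missing assay", a))
  if ("AD" %in% an) {
    d <- dim(SummarizedExperiment::assay(object, "AD"))
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "AD must be a sites x samples x 3 array")
  }
  for (cc in c("ref", "alt", "qual"))
    if (!cc %in% colnames(SummarizedExperiment::rowData(object)))
      msg <- c(msg, paste("rowData must contain", cc))
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr) > 1L) {
    pos <- GenomicRanges::start(rr)
    chr <- as.character(GenomicRanges::seqnames(rr))
    bad <- tapply(pos, chr, function(p) any(diff(p) <= 0))
    if (any(unlist(bad)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (is.null(msg)) TRUE else msg
})

#' Census of mtDNA haplotypes by species
#'
#' @slot counts named integer vector: number of distinct haplotypes per
#'   species.
#' @slot freq data.frame with columns `haplotype`, `species`, `count`.
#' @slot dist symmetric matrix of pairwise mutation-count distances between
#'   the distinct haplotypes.
#' @slot shared data.frame of haplotypes observed in more than one species.
#'
#' @export
setClass("HaplotypeCensus",
  representation(counts = "integer", freq = "data.frame", dist = "matrix",
                 shared = "data.frame"))
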