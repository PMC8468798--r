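#' Fold a site-frequency spectrum to minor-allele orientation
#'
#' Entry `i` receives the mass of entry `n - i` (1D) or `(n1 - i, n2 - j)`
#' (2D); entries beyond the fold are zeroed and their mask state is carried
#' over.  Folding an already folded spectrum is a no-op with a warning.
#'
#' @param sfs an [Sfs1D-class] or [Sfs2D-class] object.
#' @return an object of the same class, folded.
#' @export
setGeneric("fold", function(sfs) standardGeneric("fold"))

#' Mask uninformative frequency classes
#'
#' Marks the monomorphic/fixed classes and the classes where the variant is
#' present in only one sampled allele copy (singletons) as masked, mirroring
#' the treatment of spectra prior to demographic fitting.  Masked entries are
#' retained for bookkeeping but excluded from likelihoods.  Idempotent.
#'
#' @param sfs an [Sfs1D-class] or [Sfs2D-class] object.
#' @param rule masking rule; only `"singletons_and_full"` is defined.
#' @return an object of the same class with its mask updated.
#' @export
setGeneric("applyMask", function(sfs, rule = "singletons_and_full")
  standardGeneric("applyMask"))

#' Nucleotide diversity (pi)
#'
#' Average number of pairwise differences per site between sampled sequences
#' (or sampled allele copies, for genotype data), with missing data handled
#' by pairwise-complete site counts.
#'
#' @param x a [GenotypeMatrix-class] or an `ape::DNAbin` alignment.
#' @param ... method-specific arguments.
#' @return a data.frame of per-locus values plus a concatenated estimate
#'   (loci weighted by callable length).
#' @export
setGeneric("nucleotideDiversity", function(x, ...)
  standardGeneric("nucleotideDiversity"))

#' AMOVA-based Phi-ST between two populations
#'
#' Excoffier-Smouse-Quattro variance decomposition of pairwise sequence
#' differences: `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`.
#' The composite value is the decomposition of the concatenated data (ratio
#' of summed variance components), not the mean of per-locus values.
#'
#' @param x a [GenotypeMatrix-class] or an `ape::DNAbin` alignment.
#' @param populations factor/character of population labels, one per sample.
#' @param ... method-specific arguments.
#' @return a list with `composite`, per-locus and (for genotype input)
#'   per-site values, and the raw variance components.
#' @export
setGeneric("phiSt", function(x, populations, ...) standardGeneric("phiSt"))

#' Parameter confidence intervals from the observed information
#'
#' Standard errors are obtained from the numerically differentiated Fisher
#' (observed) information of the Poisson composite log-likelihood on the log
#' parameter scale; intervals are `exp(log est +/- z * SE)`.
#'
#' @param fit a converged [FitResult-class].
#' @param observed the spectrum the fit was computed from.
#' @param level confidence level (0.95 default; 0 gives zero-width
#'   intervals at the estimates).
#' @return the [FitResult-class] with `se`, `ci` and `wideCi` filled in.
#' @export
setGeneric("confidenceIntervals",
  function(fit, observed, level = 0.95) standardGeneric("confidenceIntervals"))

#' @rdname Sfs1D-class
#' @param object,sfs an SFS object.
#' @export
setGeneric("sfsEntries", function(sfs) standardGeneric("sfsEntries"))

#' @rdname Sfs1D-class
#' @export
setGeneric("sfsMask", function(sfs) standardGeneric("sfsMask"))

#' @rdname Sfs1D-class
#' @export
setGeneric("isFolded", function(sfs) standardGeneric("isFolded"))

#' @rdname Sfs1D-class
#' @export
setGeneric("seqLength", function(sfs) standardGeneric("seqLength"))

#' @rdname Sfs1D-class
#' @param value replacement value.
#' @export
setGeneric("seqLength<-", function(sfs, value) standardGeneric("seqLength<-"))
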