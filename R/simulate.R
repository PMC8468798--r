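#' Construct a study design for the cohort simulator
#'
#' Defaults describe a ddRAD-like study: median per-sample depth of 119
#' reads, modest missingness, an even sex ratio and strongly diverged
#' groups (the regime in which composite differentiation between bird
#' species is high).
#'
#' @param nSamplesPerGroup diploid samples per group.
#' @param nAutosomalSites,nZSites site counts.
#' @param nGroups number of groups (default 2).
#' @param medianDepth target median sequencing depth in reads.
#' @param missingRate flat genotype missingness in [0, 1).
#' @param sexRatio fraction of females per group.
#' @param groupAlleleFreqDivergence 0 = shared frequencies, 1 = fixed
#'   differences between groups.
#' @param depthOverdispersion negative-binomial size of the depth model.
#' @param seed integer seed.
#' @return a [StudyDesign-class].
#' @export
StudyDesign <- function(nSamplesPerGroup, nAutosomalSites, nZSites = 0L,
                        nGroups = 2L, medianDepth = 119,
                        missingRate = 0.05, sexRatio = 0.5,
                        groupAlleleFreqDivergence = 0.7,
                        depthOverdispersion = 10, seed = 1L) {
  new("StudyDesign", nGroups = as.integer(nGroups),
      nSamplesPerGroup = as.integer(nSamplesPerGroup),
      nAutosomalSites = as.integer(nAutosomalSites),
      nZSites = as.integer(nZSites), medianDepth = medianDepth,
      missingRate = missingRate, sexRatio = sexRatio,
      groupAlleleFreqDivergence = groupAlleleFreqDivergence,
      depthOverdispersion = depthOverdispersion, seed = as.integer(seed))
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(paste0(
    "StudyDesign: %d groups x %d samples, %d autosomal + %d Z sites\n",
    "  depth %g (NB size %g), missing %g, sex ratio %g, divergence %g, ",
    "seed %d\n"),
    object@nGroups, object@nSamplesPerGroup, object@nAutosomalSites,
    object@nZSites, object@medianDepth, object@depthOverdispersion,
    object@missingRate, object@sexRatio,
    object@groupAlleleFreqDivergence, object@seed))
})

## epochs in engine order (present backwards): sizes then the ancestral size
.engineEpochs <- function(model) {
  list(nu = c(rev(model@v), model@vAnc),
       dur = rev(model@t))
}

#' Simulate the mean unfolded SFS under a stepwise size model
#'
#' Hudson-style single-locus coalescent: genealogies are drawn backward in
#' time with piecewise-exponential waiting times whose rate is
#' `choose(k, 2) / nu` in the epoch covering the current time, and
#' infinite-sites mutations are sprinkled on branches as Poisson counts
#' with rate `theta / 2` per unit branch length.  Entry `i` of the result
#' is the mean count of sites whose derived allele is carried by `i` of the
#' `n` sampled copies; the per-entry standard error of that mean is
#' attached as attribute `"se"`, and `reps * entries` recovers the summed
#' counts (attribute `"nreps"`).
#'
#' @param n haploid sample size (>= 2).
#' @param model an [EpochModel-class]; the ancestral epoch is unbounded.
#' @param theta population-scaled mutation rate (> 0).
#' @param reps number of independent genealogies.
#' @param seed integer seed.
#' @param aggregate `"mean"` (default) or `"sum"` (total counts, i.e. a
#'   simulated dataset of `reps` loci).
#' @return an unfolded [Sfs1D-class].
#' @export
simulateSfs1d <- function(n, model, theta, reps = 1e5L, seed = 1L,
                          aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (n < 2L) stop("n must be >= 2")
  if (theta <= 0) stop("theta must be positive")
  if (reps < 1L) stop("reps must be >= 1")
  ep <- .engineEpochs(model)
  set.seed(seed)
  r <- .cppSimSfs1d(as.integer(n), ep$nu, ep$dur, theta, as.integer(reps),
                    TRUE)
  mean <- r$sum / reps
  se <- sqrt(pmax(r$sumsq / reps - mean^2, 0) / reps)
  ent <- c(0, if (aggregate == "mean") mean else r$sum, 0)
  out <- Sfs1D(ent)
  attr(out, "se") <- c(0, if (aggregate == "mean") se else se * reps, 0)
  attr(out, "nreps") <- reps
  attr(out, "totalTreeLength") <- r$total_length / reps
  out
}

#' Simulate the mean joint SFS under a two-population model
#'
#' Structured-coalescent simulation of two demes that merge into the
#' ancestral population at scaled time `T`; backward in time, lineages
#' migrate between demes at the scaled rates of the requested model (see
#' [pairwiseModels()]).
#'
#' @param n1,n2 haploid sample sizes.
#' @param modelName one of the registered pairwise model names.
#' @param params named or positional numeric parameter vector matching the
#'   model's arity.
#' @param theta population-scaled mutation rate.
#' @param reps number of genealogies.
#' @param seed integer seed.
#' @param aggregate `"mean"` or `"sum"` as in [simulateSfs1d()].
#' @return an unfolded [Sfs2D-class] with attribute `"se"`.
#' @export
simulateSfs2d <- function(n1, n2, modelName, params = numeric(),
                          theta = 1, reps = 2e4L, seed = 1L,
                          aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  spec <- .pairwiseModel(modelName)
  args <- spec$simArgs(.checkParams(spec, params))
  set.seed(seed)
  r <- .cppSimSfs2d(as.integer(n1), as.integer(n2), args$nu1, args$nu2,
                    args$Tsplit, args$m12, args$m21, args$nuAnc, theta,
                    as.integer(reps), TRUE)
  mean <- r$sum / reps
  se <- sqrt(pmax(r$sumsq / reps - mean^2, 0) / reps)
  out <- Sfs2D(if (aggregate == "mean") mean else r$sum)
  attr(out, "se") <- if (aggregate == "mean") se else se * reps
  attr(out, "nreps") <- reps
  out
}

#' Simulate a ddRAD-like genotype matrix with known truth
#'
#' Diploid genotypes are drawn from group-specific allele frequencies
#' (`p_g = (1 - d) * p0 + d * fix_g`, where `d` is the divergence fraction
#' and `fix_g` alternates 0/1 across groups, so `d = 1` yields fixed
#' differences).  Read depths are negative-binomial around the target
#' median; females are hemizygous at Z sites - a single allele is drawn,
#' reported as a homozygous call, and recovered at half depth, mimicking a
#' variant caller run on hemizygous data.  A flat `missingRate` removes
#' genotypes at random.
#'
#' @param design a [StudyDesign-class].
#' @return list with `genotypes` (a [GenotypeMatrix-class]) and `truth`
#'   (a [SimTruth-class]).
#' @export
simulateGenotypeMatrix <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  validObject(design)
  set.seed(design@seed)
  G <- design@nGroups
  nPer <- design@nSamplesPerGroup
  nS <- G * nPer
  nA <- design@nAutosomalSites
  nZ <- design@nZSites
  nSite <- nA + nZ
  group <- rep(paste0("group", seq_len(G)), each = nPer)
  ids <- sprintf("%s_s%02d", group, sequence(rep(nPer, G)))
  nFem <- round(design@sexRatio * nPer)
  sex <- unlist(lapply(seq_len(G), function(g)
    c(rep("female", nFem), rep("male", nPer - nFem))))
  # group allele frequencies
  p0 <- runif(nSite, 0.1, 0.9)
  d <- design@groupAlleleFreqDivergence
  fixg <- (seq_len(G) - 1L) %% 2L
  freqs <- vapply(seq_len(G), function(g) (1 - d) * p0 + d * fixg[g],
                  numeric(nSite))
  nAut <- 5L
  chrom <- c(paste0("chr", rep(seq_len(nAut), length.out = nA)),
             rep("chrZ", nZ))
  pos <- integer(nSite)
  for (ch in unique(chrom)) {
    k <- chrom == ch
    pos[k] <- sort(sample.int(1e7L, sum(k)))
  }
  isZ <- chrom == "chrZ"
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nSite, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  gt1 <- gt2 <- matrix(NA_integer_, nSite, nS)
  ad <- array(NA_real_, c(nSite, nS, 3L))
  fem <- sex == "female"
  for (s in seq_len(nS)) {
    p <- freqs[, match(group[s], paste0("group", seq_len(G)))]
    a1 <- rbinom(nSite, 1L, p)
    a2 <- rbinom(nSite, 1L, p)
    if (fem[s] && any(isZ)) a2[isZ] <- a1[isZ]  # hemizygous, reported hom
    mu <- rep(design@medianDepth, nSite)
    if (fem[s]) mu[isZ] <- mu[isZ] / 2
    dp <- rnbinom(nSite, size = design@depthOverdispersion, mu = mu)
    het <- a1 != a2
    adAlt <- integer(nSite)
    adAlt[het] <- rbinom(sum(het), dp[het], 0.5)
    adAlt[!het & a1 == 1L] <- dp[!het & a1 == 1L]
    adRef <- dp - adAlt
    miss <- runif(nSite) < design@missingRate | dp == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    adRef[miss] <- NA_integer_; adAlt[miss] <- NA_integer_
    gt1[, s] <- pmin(a1, a2)
    gt2[, s] <- pmax(a1, a2)
    ad[, s, 1L] <- adRef
    ad[, s, 2L] <- adAlt
  }
  qual <- pmin(pmax(round(rnorm(nSite, 60, 5)), 35), 99)
  gm <- GenotypeMatrix(chrom, pos, ref, alt, qual, gt1, gt2, ad, ids,
                       group = group)
  truth <- new("SimTruth", sex = setNames(sex, ids),
               group = setNames(group, ids),
               alleleFreqs = freqs[order(chrom, pos), , drop = FALSE],
               design = design)
  list(genotypes = gm, truth = truth)
}

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d samples (%d female), %d sites x %d groups\n",
              length(object@sex), sum(object@sex == "female"),
              nrow(object@alleleFreqs), ncol(object@alleleFreqs)))
})

#' Write the truth table of a simulated cohort as TSV
#'
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
  df <- data.frame(sampleId = names(truth@sex), group = truth@group,
                   sex = truth@sex)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
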