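#' Registry of two-population demographic models
#'
#' Three classical models on a population split at scaled time `T` before
#' present, plus the no-migration constrained variant:
#' \describe{
#'   \item{neutral_no_divergence}{the two samples are arbitrary partitions
#'     of one panmictic population; no parameters.}
#'   \item{split_migration}{sizes `nu1`, `nu2`, split time `T`, symmetric
#'     scaled migration `m`.}
#'   \item{isolation_with_migration}{sizes `nu1`, `nu2`, split time `T`,
#'     asymmetric `m12` (into population 1) and `m21`.}
#'   \item{split_no_migration}{`split_migration` constrained to `m = 0`.}
#' }
#' Migration rates follow the diffusion convention: `m12` is the scaled
#' rate at which population 1 receives migrants from population 2, so the
#' expected number of migrant lineages per generation into population 1 is
#' `m12 * nu1 / 2`.
#'
#' @return named list of model specifications (`npar`, `parNames`,
#'   `simArgs`).
#' @export
pairwiseModels <- function() {
  list(
    neutral_no_divergence = list(
      npar = 0L, parNames = character(),
      simArgs = function(p) list(nu1 = 1, nu2 = 1, Tsplit = 0, m12 = 0,
                                 m21 = 0, nuAnc = 1)),
    split_migration = list(
      npar = 4L, parNames = c("nu1", "nu2", "T", "m"),
      simArgs = function(p) list(nu1 = p[1], nu2 = p[2], Tsplit = p[3],
                                 m12 = p[4], m21 = p[4], nuAnc = 1)),
    isolation_with_migration = list(
      npar = 5L, parNames = c("nu1", "nu2", "T", "m12", "m21"),
      simArgs = function(p) list(nu1 = p[1], nu2 = p[2], Tsplit = p[3],
                                 m12 = p[4], m21 = p[5], nuAnc = 1)),
    split_no_migration = list(
      npar = 3L, parNames = c("nu1", "nu2", "T"),
      simArgs = function(p) list(nu1 = p[1], nu2 = p[2], Tsplit = p[3],
                                 m12 = 0, m21 = 0, nuAnc = 1)))
}

## canonical-cell index map implementing the 2D fold: each unfolded cell is
## sent to the linear (column-major) index of its fold representative
.fold2dMap <- function(n1, n2, folded = TRUE) {
  ncell <- (n1 + 1L) * (n2 + 1L)
  if (!folded) return(seq_len(ncell))
  out <- integer(ncell)
  ntot <- n1 + n2
  for (j in 0:n2) {
    for (i in 0:n1) {
      lin <- j * (n1 + 1L) + i + 1L
      ic <- n1 - i; jc <- n2 - j; tot <- i + j
      keep <- (2L * tot < ntot) ||
        (2L * tot == ntot && (i < ic || (i == ic && j <= jc)))
      out[lin] <- if (keep) lin else jc * (n1 + 1L) + ic + 1L
    }
  }
  out
}

.pairwiseModel <- function(name) {
  reg <- pairwiseModels()
  if (!name %in% names(reg))
    stop("unknown pairwise model: ", name, " (registered: ",
         paste(names(reg), collapse = ", "), ")")
  c(reg[[name]], list(name = name))
}

.checkParams <- function(spec, params) {
  if (length(params) != spec$npar)
    stop(sprintf("model %s expects %d parameter(s), got %d", spec$name,
                 spec$npar, length(params)))
  if (!is.null(names(params)) && length(params) &&
      !identical(names(params), spec$parNames))
    params <- params[spec$parNames]
  if (anyNA(params)) stop("parameters do not match the model's names")
  as.numeric(params)
}

#' Expected joint SFS under a two-population model
#'
#' For `neutral_no_divergence` the expectation is deterministic: the
#' single-population spectrum for `n1 + n2` copies distributed into the two
#' samples with hypergeometric weights.  For the split models it is the
#' average over `reps` structured-coalescent genealogies of the expected
#' mutation mass per joint frequency class (branch-length averaging, no
#' Poisson noise).
#'
#' @param modelName registered model name.
#' @param params parameter vector matching the model's arity.
#' @param n1,n2 haploid sample sizes (>= 4).
#' @param theta scaled mutation multiplier (default 1: relative spectrum).
#' @param reps genealogy replicates for the Monte Carlo expectation.
#' @param seed integer seed (common random numbers across calls with equal
#'   seed).
#' @return an unfolded [Sfs2D-class].
#' @export
expectedSfs2d <- function(modelName, params = numeric(), n1, n2,
                          theta = 1, reps = 2e4L, seed = 1L) {
  spec <- .pairwiseModel(modelName)
  params <- .checkParams(spec, params)
  if (n1 < 4L || n2 < 4L) stop("n1 and n2 must be >= 4")
  if (modelName == "neutral_no_divergence") {
    ntot <- n1 + n2
    xi <- sfsEntries(expectedSfsStepwise(EpochModel(v = 1, t = 0.1),
                                         ntot, theta = theta))
    ent <- matrix(0, n1 + 1L, n2 + 1L)
    for (b in seq_len(ntot - 1L)) {
      i <- max(0L, b - n2):min(n1, b)
      ent[cbind(i + 1L, b - i + 1L)] <- xi[b + 1L] * dhyper(i, n1, n2, b)
    }
    return(Sfs2D(ent))
  }
  args <- spec$simArgs(params)
  set.seed(seed)
  r <- .cppSimSfs2d(as.integer(n1), as.integer(n2), args$nu1, args$nu2,
                    args$Tsplit, args$m12, args$m21, args$nuAnc, theta,
                    as.integer(reps), FALSE)
  m <- r$sum / reps
  out <- Sfs2D(m)
  attr(out, "se") <- sqrt(pmax(r$sumsq / reps - m^2, 0) / reps)
  out
}

## expectation folded/masked to match an observed spectrum; optionally carry
## the folded Monte Carlo variance of each cell (variances added across the
## aggregated fold pair, covariance neglected)
.pairwiseExpectation <- function(modelName, params, n, observed, reps,
                                 seed, withVar = FALSE) {
  ex <- expectedSfs2d(modelName, params, n[1], n[2], reps = reps,
                      seed = seed)
  se <- attr(ex, "se")
  if (modelName != "neutral_no_divergence" && reps > 0) {
    # continuity floor: an unobserved class is credited less than one
    # genealogy's worth of mass so finite counts never meet log(0)
    ex@entries <- pmax(ex@entries, 0.25 / reps)
  }
  out <- .matchExpectation(ex, observed)
  if (withVar) {
    v2 <- if (is.null(se)) matrix(0, n[1] + 1L, n[2] + 1L) else se^2
    vf <- .matchExpectation(Sfs2D(v2, folded = FALSE), observed)
    attr(out, "mcVar") <- sfsEntries(vf)
  }
  out
}

## delta-method correction of the Jensen bias that Monte Carlo noise in the
## expected spectrum induces in sum k * log(m_hat): adds k * Var(m_hat) /
## (2 m_hat^2) over the unmasked support
.jensenCorrection <- function(observed, ex) {
  v <- attr(ex, "mcVar")
  if (is.null(v)) return(0)
  use <- !sfsMask(observed) & sfsEntries(ex) > 0
  sum(sfsEntries(observed)[use] * v[use] / (2 * sfsEntries(ex)[use]^2))
}

#' Fit a two-population model to an observed joint SFS
#'
#' Multi-start Nelder-Mead maximization of the Poisson composite
#' likelihood on log parameters, with theta profiled analytically.  The
#' Monte Carlo expectation uses common random numbers (one seed per fit)
#' so the likelihood surface is deterministic given `seed`; the final
#' log-likelihood reported for model comparison is re-evaluated at the
#' optimum with `evalReps` fresh replicates.
#'
#' @param observed an [Sfs2D-class] (typically folded and masked).
#' @param modelName registered model name.
#' @param nStarts optimizer starts.
#' @param seed integer seed.
#' @param bounds named list of `c(lower, upper)` natural-scale bounds for
#'   `nu`, `T` and `m`; a degenerate `m = c(0, 0)` bound fixes migration
#'   at zero (equivalent to `split_no_migration`).
#' @param fitReps Monte Carlo replicates per likelihood evaluation during
#'   optimization.
#' @param evalReps replicates for the final likelihood (a delta-method
#'   correction removes the Jensen bias the residual Monte Carlo noise
#'   would otherwise leave in `sum k log m`).
#' @param polish refine the best coarse start on a finer Monte Carlo
#'   surface (`polishReps` replicates per evaluation).
#' @param polishReps replicates per evaluation during polishing.
#' @param computeCi compute FIM standard errors (adds Hessian
#'   evaluations at `hessianReps` replicates each).
#' @param hessianReps replicates per Hessian evaluation.
#' @param level confidence level for intervals.
#' @return a [FitResult-class].
#' @export
fitPairwise <- function(observed, modelName, nStarts = 10L, seed = 1L,
                        bounds = list(nu = c(1e-2, 1e2), T = c(1e-3, 5),
                                      m = c(1e-3, 10)),
                        fitReps = 2000L, evalReps = 50000L,
                        polish = TRUE, polishReps = 5L * fitReps,
                        computeCi = TRUE, hessianReps = 5000L,
                        level = 0.95) {
  stopifnot(is(observed, "Sfs2D"))
  spec <- .pairwiseModel(modelName)
  n <- sampleSizes(observed)
  crnSeed <- as.integer((seed * 7919L) %% 2147483L + 1L)
  evalSeed <- crnSeed + 104729L
  if (modelName == "neutral_no_divergence") {
    ex <- .pairwiseExpectation(modelName, numeric(), n, observed,
                               reps = 0L, seed = evalSeed)
    ll <- compositeLogLik(observed, ex)
    obs <- c(.obsSummary(observed),
             list(crnSeed = evalSeed, evalReps = 0L))
    return(new("FitResult", modelName = modelName, params = numeric(),
               theta = attr(ll, "theta"), loglik = as.numeric(ll),
               se = c(theta = NA_real_),
               ci = matrix(NA_real_, 1L, 2L,
                           dimnames = list("theta", c("lower", "upper"))),
               epochModel = NULL, nStarts = 0L,
               starts = data.frame(start = integer(), loglik = numeric(),
                                   convergence = integer()),
               converged = TRUE, seed = as.integer(seed),
               obsSummary = obs))
  }
  fixZeroM <- !is.null(bounds$m) && all(bounds$m == 0)
  pn <- spec$parNames
  isM <- grepl("^m", pn)
  free <- if (fixZeroM) which(!isM) else seq_along(pn)
  boundOf <- function(p) {
    if (grepl("^nu", p)) bounds$nu else if (p == "T") bounds$T else bounds$m
  }
  lo <- log(vapply(pn[free], function(p) boundOf(p)[1], 0))
  hi <- log(vapply(pn[free], function(p) boundOf(p)[2], 0))
  assemble <- function(lpFree) {
    full <- setNames(numeric(length(pn)), pn)
    full[free] <- exp(lpFree)
    full[setdiff(seq_along(pn), free)] <- 0
    full
  }
  ## fast likelihood path: fold the raw Monte Carlo matrix onto the
  ## observed layout with a precomputed index map, no S4 in the hot loop
  foldMap <- .fold2dMap(n[1], n[2], folded = isFolded(observed))
  grp <- sort(unique(foldMap))
  kObs <- as.vector(sfsEntries(observed))
  mskObs <- as.vector(sfsMask(observed))
  fastNegll <- function(lpFree, reps) {
    pen <- .boxPenalty(lpFree, lo, hi)
    lpFree <- pmin(pmax(lpFree, lo), hi)
    args <- spec$simArgs(assemble(lpFree))
    set.seed(crnSeed)
    r <- tryCatch(
      .cppSimSfs2d(n[1], n[2], args$nu1, args$nu2, args$Tsplit,
                   args$m12, args$m21, args$nuAnc, 1, as.integer(reps),
                   FALSE, 500),
      error = function(e) NULL)
    if (is.null(r)) return(1e10)
    fe <- numeric(length(kObs))
    fe[grp] <- rowsum(as.vector(r$sum) / reps, foldMap)
    fe[grp] <- pmax(fe[grp], 0.5 / reps)
    use <- !mskObs & !(fe == 0 & kObs == 0)
    theta <- sum(kObs[use]) / sum(fe[use])
    mu <- theta * fe[use]
    -sum(kObs[use] * log(mu) - mu - lgamma(kObs[use] + 1)) + pen
  }
  base <- setNames(rep(0, length(free)), pn[free])
  base[pn[free] == "T"] <- log(0.5)
  base[isM[free]] <- log(0.5)
  starts <- data.frame(start = integer(), loglik = numeric(),
                       convergence = integer())
  ends <- list()
  for (j in seq_len(nStarts)) {
    set.seed(seed + j)
    p0 <- base + rnorm(length(free))
    opt <- optim(p0, fastNegll, reps = fitReps, method = "Nelder-Mead",
                 control = list(maxit = 150, reltol = 1e-7))
    starts <- rbind(starts, data.frame(start = j, loglik = -opt$value,
                                       convergence = opt$convergence))
    ends[[j]] <- opt
  }
  ## re-rank the start endpoints on a finer surface before polishing
  rankReps <- max(10L * fitReps, 10000L)
  rescore <- vapply(ends, function(o) fastNegll(o$par, rankReps), 0)
  best <- ends[[which.min(rescore)]]
  if (!is.finite(min(rescore)) || min(rescore) >= 1e10)
    stop("no optimizer start converged for model ", modelName)
  if (polish) {
    opt <- optim(best$par, fastNegll, reps = as.integer(polishReps),
                 method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
    starts <- rbind(starts, data.frame(start = NA_integer_,
                                       loglik = -opt$value,
                                       convergence = opt$convergence))
    best <- opt
  }
  lp <- pmin(pmax(best$par, lo), hi)
  params <- assemble(lp)
  ex <- .pairwiseExpectation(modelName, params, n, observed,
                             reps = evalReps, seed = evalSeed,
                             withVar = TRUE)
  ll <- compositeLogLik(observed, ex)
  ll <- structure(as.numeric(ll) + .jensenCorrection(observed, ex),
                  theta = attr(ll, "theta"))
  keep <- params[free]
  obs <- c(.obsSummary(observed),
           list(crnSeed = crnSeed, evalReps = as.integer(hessianReps)))
  fit <- new("FitResult", modelName = modelName, params = keep,
             theta = attr(ll, "theta"), loglik = as.numeric(ll),
             se = setNames(rep(NA_real_, length(keep) + 1L),
                           c(names(keep), "theta")),
             ci = matrix(NA_real_, length(keep) + 1L, 2L,
                         dimnames = list(c(names(keep), "theta"),
                                         c("lower", "upper"))),
             epochModel = NULL, nStarts = as.integer(nStarts),
             starts = starts, converged = any(starts$convergence == 0L),
             seed = as.integer(seed), obsSummary = obs)
  if (computeCi)
    fit <- tryCatch(confidenceIntervals(fit, observed, level = level),
                    error = function(e) { fit@wideCi <- TRUE; fit })
  fit
}

#' Rank candidate two-population fits by AIC
#'
#' `AIC = 2 * npar - 2 * loglik` with parameter counts from the model
#' registry; ties in AIC are broken toward the model with fewer
#' parameters.  All fits must have been computed from the same observed
#' spectrum.
#'
#' @param fits list of [FitResult-class] objects on the same data.
#' @return data.frame ranked by AIC with `dAIC` relative to the best.
#' @export
selectModel <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to rank")
  keys <- lapply(fits, function(f) f@obsSummary[c("n", "checksum")])
  if (!all(vapply(keys[-1], identical, TRUE, keys[[1]])))
    stop("fits were computed from different observed spectra")
  reg <- pairwiseModels()
  npar <- vapply(fits, function(f)
    if (f@modelName %in% names(reg)) reg[[f@modelName]]$npar
    else length(f@params), 0L)
  ll <- vapply(fits, slot, 0, "loglik")
  aic <- 2 * npar - 2 * ll
  out <- data.frame(model = vapply(fits, slot, "", "modelName"),
                    npar = npar, loglik = ll, AIC = aic)
  out <- out[order(out$AIC, out$npar), ]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

#' Convert a scaled migration rate to migrants per generation
#'
#' Under the adopted convention (`m_ij` = scaled rate of migration into
#' population `i`, sizes relative to the ancestral population, time in
#' `2 N_ANC` generations) the expected number of migrant lineages entering
#' population `i` each generation is `M = m_ij * nu_i / 2`.
#'
#' @param fit a pairwise [FitResult-class].
#' @param receivingPop 1 or 2.
#' @return migrants per generation (0 for models without migration).
#' @export
migrantsPerGeneration <- function(fit, receivingPop = 1L) {
  stopifnot(is(fit, "FitResult"))
  p <- fit@params
  m <- if ("m" %in% names(p)) p[["m"]]
  else if (receivingPop == 1L && "m12" %in% names(p)) p[["m12"]]
  else if (receivingPop == 2L && "m21" %in% names(p)) p[["m21"]]
  else 0
  nuName <- paste0("nu", receivingPop)
  nu <- if (nuName %in% names(p)) p[[nuName]] else 1
  unname(m * nu / 2)
}

#' Invert [migrantsPerGeneration()]
#'
#' @param M migrants per generation.
#' @param nuReceiving relative size of the receiving population.
#' @return the scaled migration rate `m = 2 M / nu`.
#' @export
scaledMigrationRate <- function(M, nuReceiving) 2 * M / nuReceiving

`%||%` <- function(a, b) if (is.null(a)) b else a
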