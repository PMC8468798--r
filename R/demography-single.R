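#' Construct an EpochModel
#'
#' @param v positive relative sizes, earliest first.
#' @param t non-negative scaled durations (units of `2 * N_ANC`
#'   generations), parallel to `v`.
#' @param vAnc ancestral relative size (1 by normalization).
#' @param tAnc scaled duration of the ancestral period (rendering only).
#' @return an [EpochModel-class].
#' @examples
#' constantModel <- EpochModel(v = 1, t = 0.5)
#' expansion <- EpochModel(v = 10, t = 0.1)  # tenfold recent expansion
#' @export
EpochModel <- function(v, t, vAnc = 1, tAnc = 0) {
  new("EpochModel", v = as.numeric(v), t = as.numeric(t),
      vAnc = as.numeric(vAnc), tAnc = as.numeric(tAnc))
}

setMethod("show", "EpochModel", function(object) {
  cat(sprintf(
    "EpochModel: %d steps, total scaled time %.4g (+ ancestral %.4g)\n",
    length(object@v), sum(object@t), object@tAnc))
  cat(sprintf("  size range [%.4g, %.4g] x N_ANC\n",
              min(object@v), max(object@v)))
})

#' Render control points into a stepwise model
#'
#' Expands `K` control points into `nSteps` equal-duration-per-segment
#' steps.  Segment `k` spans duration `t[k]` and its step sizes are
#' interpolated (geometrically, by default) from the previous node's size
#' (the ancestral size 1 for the first segment) to `v[k]`, so the most
#' recent rendered step has size `v[K]` and the model describes a
#' continuous size transformation.
#'
#' @param v,t control-point sizes and segment durations, earliest first.
#' @param nSteps total number of rendered steps (default 100).
#' @param interp `"geometric"` (log-linear in time) or `"step"`
#'   (piecewise-constant at the node values).
#' @param tAnc ancestral duration carried through for rendering.
#' @return an [EpochModel-class] with `nSteps` steps.
#' @export
renderEpochModel <- function(v, t, nSteps = 100L, interp = c("geometric",
                                                             "step"),
                             tAnc = 0) {
  interp <- match.arg(interp)
  K <- length(v)
  stopifnot(length(t) == K, K >= 1L, nSteps >= K)
  per <- rep(nSteps %/% K, K)
  extra <- nSteps - sum(per)
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  sv <- numeric(0)
  st <- numeric(0)
  prev <- 1  # ancestral size
  for (k in seq_len(K)) {
    frac <- (seq_len(per[k]) - 0.5) / per[k]
    sizes <- if (interp == "geometric")
      exp(log(prev) + frac * (log(v[k]) - log(prev)))
    else rep(v[k], per[k])
    sv <- c(sv, sizes)
    st <- c(st, rep(t[k] / per[k], per[k]))
    prev <- v[k]
  }
  EpochModel(v = sv, t = st, tAnc = tAnc)
}

#' Expected SFS under the stepwise size model
#'
#' Deterministic expectation of the unfolded site-frequency spectrum under
#' the piecewise-constant coalescent.  The expected time `W_k` during which
#' the genealogy has `k` ancestral lineages is obtained by integrating the
#' occupancy of the pure-death coalescent chain through the epochs
#' (uniformization in rescaled time; no grid, no Euler stepping), and
#'
#'   `E[xi_i] = (theta / 2) * sum_k k * W_k * P(i | n, k)`
#'
#' with the classical polynomial probability that a branch carrying `k`
#' ancestral lineages subtends `i` of `n` samples.  With all sizes equal to
#' 1 this reduces to `E[xi_i] = theta / i` exactly.
#'
#' @param model an [EpochModel-class].
#' @param n haploid sample size (>= 4).
#' @param theta scaled mutation rate multiplier (default 1, i.e. a
#'   relative spectrum).
#' @return an unfolded [Sfs1D-class].
#' @export
expectedSfsStepwise <- function(model, n, theta = 1) {
  stopifnot(is(model, "EpochModel"))
  validObject(model)
  if (n < 4L) stop("n must be >= 4")
  if (any(model@v < 1e-8) || model@vAnc < 1e-8)
    stop("degenerate epoch size (v ~ 0): expectation is numerically undefined")
  ep <- .engineEpochs(model)
  W <- .cppOccupancy(as.integer(n), ep$nu, ep$dur)
  ent <- numeric(n + 1L)
  for (i in seq_len(n - 1L)) {
    k <- 2:(n - i + 1L)
    ent[i + 1L] <- (theta / 2) *
      sum(k * W[k - 1L] * exp(lchoose(n - i - 1L, k - 2L) -
                                lchoose(n - 1L, k - 1L)))
  }
  Sfs1D(ent)
}

## align a relative expectation with an observed spectrum: fold and copy mask
.matchExpectation <- function(expected, observed) {
  if (isFolded(observed) && !isFolded(expected))
    expected <- fold(expected)
  if (isFolded(expected) != isFolded(observed))
    stop("fold state mismatch between observed and expected spectra")
  expected@mask <- sfsMask(observed)
  expected
}

.poissonCompLL <- function(k, m, theta = NULL) {
  # k observed counts, m relative expectations, over unmasked support
  if (!length(k) || sum(m) <= 0)
    stop("empty support: every informative entry is masked")
  if (is.null(theta)) theta <- sum(k) / sum(m)
  mu <- theta * m
  ll <- sum(ifelse(k == 0 & mu == 0, 0, k * log(mu) - mu - lgamma(k + 1)))
  attr(ll, "theta") <- theta
  ll
}

#' Poisson composite log-likelihood of an observed SFS
#'
#' `sum_i [k_i log(theta m_i) - theta m_i - log k_i!]` over unmasked
#' entries, treating sites as independent.  When `theta` is `NULL` it is
#' profiled analytically (`theta_hat = sum k / sum m`) and returned as
#' attribute `"theta"`.
#'
#' @param observed,expectedRel spectra of matching type, sample size, fold
#'   state and mask; `expectedRel` is the relative (theta = 1) expectation.
#' @param theta fixed scaled mutation rate, or `NULL` to profile.
#' @return the log-likelihood with attribute `"theta"`.
#' @export
compositeLogLik <- function(observed, expectedRel, theta = NULL) {
  if (!identical(class(observed), class(expectedRel)))
    stop("observed and expected spectra must be of the same class")
  if (!identical(sampleSizes(observed), sampleSizes(expectedRel)))
    stop("sample size mismatch")
  if (isFolded(observed) != isFolded(expectedRel))
    stop("fold state mismatch")
  if (!identical(sfsMask(observed), sfsMask(expectedRel)))
    stop("mask mismatch")
  use <- !sfsMask(observed)
  .poissonCompLL(as.vector(sfsEntries(observed))[as.vector(use)],
                 as.vector(sfsEntries(expectedRel))[as.vector(use)], theta)
}

.obsSummary <- function(observed) {
  list(class = class(observed), n = sampleSizes(observed),
       folded = isFolded(observed),
       checksum = sum(sfsEntries(observed) * seq_along(sfsEntries(observed))),
       total = sum(sfsEntries(observed)))
}

.boxPenalty <- function(lp, lo, hi) {
  1e4 * sum(pmax(lp - hi, 0)^2 + pmax(lo - lp, 0)^2)
}

#' Fit the stepwise size model to a folded, masked SFS
#'
#' Multi-start bounded optimization of the Poisson composite likelihood
#' over `nFreeSizes` control points (sizes and segment durations, both on
#' the log scale; theta is profiled analytically).  Start `j` perturbs the
#' neutral starting point by one log-unit of seeded Gaussian noise, so the
#' best result over the first `j` starts is reproducible and non-decreasing
#' in `nStarts`.
#'
#' @param observed a folded, masked [Sfs1D-class].
#' @param nFreeSizes number of control points `K` (default 10).
#' @param nSteps rendered steps for the size trajectory (default 100).
#' @param nStarts optimizer starts (default 50).
#' @param bounds list with elements `v` and `t`, each `c(lower, upper)` on
#'   the natural scale.
#' @param seed integer seed.
#' @param interp interpolation mode passed to [renderEpochModel()].
#' @param regLambda weight of a mild ridge penalty `lambda * sum(log v)^2`
#'   that pins likelihood-flat directions (sizes whose durations shrink to
#'   nothing) at the ancestral size; negligible against informative data.
#' @param level confidence level for the reported intervals.
#' @return a [FitResult-class]; slot `epochModel` holds the rendered
#'   best-fit trajectory.
#' @seealso [confidenceIntervals()], [scaleFit()]
#' @export
fitStepwise <- function(observed, nFreeSizes = 10L, nSteps = 100L,
                        nStarts = 50L, bounds = list(v = c(1e-3, 1e3),
                                                     t = c(1e-4, 5)),
                        seed = 1L, interp = "geometric",
                        regLambda = 0.5, level = 0.95) {
  stopifnot(is(observed, "Sfs1D"))
  if (nStarts < 1L) stop("nStarts must be >= 1")
  n <- sampleSizes(observed)
  K <- as.integer(nFreeSizes)
  lo <- c(rep(log(bounds$v[1]), K), rep(log(bounds$t[1]), K))
  hi <- c(rep(log(bounds$v[2]), K), rep(log(bounds$t[2]), K))
  negll <- function(lp) {
    pen <- .boxPenalty(lp, lo, hi)
    lp <- pmin(pmax(lp, lo), hi)
    model <- renderEpochModel(exp(lp[1:K]), exp(lp[K + 1:K]),
                              nSteps = nSteps, interp = interp)
    ex <- .matchExpectation(expectedSfsStepwise(model, n), observed)
    ll <- tryCatch(compositeLogLik(observed, ex),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    # mild ridge toward the ancestral size: resolves likelihood-flat
    # directions (an extreme size over a negligible duration leaves the
    # spectrum unchanged) without biasing informative parameters
    -as.numeric(ll) + pen + regLambda * sum(lp[1:K]^2)
  }
  base <- c(rep(0, K), rep(log(0.2), K))
  starts <- data.frame(start = integer(), loglik = numeric(),
                       convergence = integer())
  best <- NULL
  for (j in seq_len(nStarts)) {
    set.seed(seed + j)
    p0 <- base + rnorm(2L * K)
    opt <- optim(p0, negll, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-10))
    starts <- rbind(starts, data.frame(start = j, loglik = -opt$value,
                                       convergence = opt$convergence))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("no optimizer start converged; per-start diagnostics:\n",
         paste(capture.output(print(starts)), collapse = "\n"))
  lp <- pmin(pmax(best$par, lo), hi)
  vHat <- exp(lp[1:K]); tHat <- exp(lp[K + 1:K])
  model <- renderEpochModel(vHat, tHat, nSteps = nSteps, interp = interp)
  ex <- .matchExpectation(expectedSfsStepwise(model, n), observed)
  ll <- compositeLogLik(observed, ex)
  params <- setNames(c(vHat, tHat),
                     c(paste0("v", seq_len(K)), paste0("t", seq_len(K))))
  fit <- new("FitResult", modelName = "stepwise", params = params,
             theta = attr(ll, "theta"), loglik = as.numeric(ll),
             se = setNames(rep(NA_real_, 2L * K + 1L),
                           c(names(params), "theta")),
             ci = matrix(NA_real_, 2L * K + 1L, 2L,
                         dimnames = list(c(names(params), "theta"),
                                         c("lower", "upper"))),
             epochModel = model, nStarts = as.integer(nStarts),
             starts = starts, converged = any(starts$convergence == 0L),
             seed = as.integer(seed),
             obsSummary = c(.obsSummary(observed),
                            list(interp = interp, nSteps = nSteps)))
  fit <- tryCatch(confidenceIntervals(fit, observed, level = level),
                  error = function(e) { fit@wideCi <- TRUE; fit })
  fit
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: loglik = %.4f, theta = %.6g, %d start(s)%s\n",
              object@modelName, object@loglik, object@theta,
              object@nStarts,
              if (object@wideCi) " [singular information: wide CIs]" else ""))
  if (length(object@params)) {
    est <- data.frame(estimate = object@params,
                      lower = object@ci[names(object@params), "lower"],
                      upper = object@ci[names(object@params), "upper"])
    print(format(est, digits = 4))
  }
})

## rebuild the relative expectation of any fitted model at given log-params
.fitExpectation <- function(fit, observed, lpar) {
  K <- length(fit@params) / 2L
  if (fit@modelName == "stepwise") {
    model <- renderEpochModel(exp(lpar[1:K]), exp(lpar[K + 1:K]),
                              nSteps = length(fit@epochModel@v),
                              interp = fit@obsSummary$interp %||% "geometric")
    .matchExpectation(expectedSfsStepwise(model, sampleSizes(observed)),
                      observed)
  } else {
    spec <- .pairwiseModel(fit@modelName)
    full <- setNames(rep(0, spec$npar), spec$parNames)
    full[names(fit@params)] <- exp(lpar)
    .pairwiseExpectation(fit@modelName, full, sampleSizes(observed),
                         observed, reps = fit@obsSummary$evalReps,
                         seed = fit@obsSummary$crnSeed)
  }
}

setMethod("confidenceIntervals", "FitResult",
  function(fit, observed, level = 0.95) {
    if (!isTRUE(all.equal(.obsSummary(observed)[c("n", "checksum")],
                          fit@obsSummary[c("n", "checksum")])))
      stop("fit was not computed from this spectrum")
    est <- fit@params
    lpar <- log(est)
    full <- c(lpar, logTheta = log(fit@theta))
    nll <- function(p) {
      np <- length(est)
      ex <- .fitExpectation(fit, observed, p[seq_len(np)])
      -as.numeric(compositeLogLik(observed, ex,
                                  theta = exp(p[np + 1L])))
    }
    H <- pracma::hessian(nll, full)
    wide <- FALSE
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
      V <- MASS::ginv(H)
      wide <- TRUE
    }
    se <- sqrt(pmax(diag(V), 0))
    if (any(!is.finite(se))) wide <- TRUE
    z <- if (level <= 0) 0 else qnorm(1 - (1 - level) / 2)
    centre <- c(est, theta = fit@theta)
    ci <- cbind(lower = centre * exp(-z * se), upper = centre * exp(z * se))
    rownames(ci) <- c(names(est), "theta")
    fit@se <- setNames(se, c(names(est), "theta"))
    fit@ci <- ci
    fit@wideCi <- wide
    fit
  })

#' Most recent fitted effective size (relative to ancestral)
#'
#' @param fit a stepwise [FitResult-class].
#' @return the relative size of the most recent rendered step.
#' @export
recentSize <- function(fit) {
  stopifnot(is(fit, "FitResult"), !is.null(fit@epochModel))
  fit@epochModel@v[length(fit@epochModel@v)]
}

#' Export the fitted trajectory as a data.frame
#'
#' One row per rendered step, earliest first, with scaled times measured
#' backwards from the present (the most recent step ends at time 0).
#'
#' @param fit a stepwise [FitResult-class].
#' @return data.frame with columns `step`, `tStart`, `tEnd` (scaled time
#'   before present) and `v` (size relative to ancestral).
#' @export
fitTrajectory <- function(fit) {
  stopifnot(is(fit, "FitResult"), !is.null(fit@epochModel))
  m <- fit@epochModel
  nsteps <- length(m@v)
  # steps are earliest-first; cumulative time from the present backwards
  endsBack <- rev(cumsum(rev(m@t))) - m@t  # time BP at each step's recent end
  data.frame(step = seq_len(nsteps) - 1L,
             tStart = endsBack + m@t, tEnd = endsBack, v = m@v)
}
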