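#' Generation time from age at maturity and adult survival
#'
#' Mean age of parents under constant adult survival: a bird first breeds
#' at age `alpha` and survives each further year with probability `s`, so
#' `G = alpha + s / (1 - s)` (the mean of the geometric number of extra
#' breeding years).
#'
#' @param alpha age at sexual maturity in years (>= 0).
#' @param survival adult annual survival fraction in (0, 1).
#' @return generation time in years.
#' @examples
#' generationTime(1, 0.5)  # 2 years
#' @export
generationTime <- function(alpha, survival) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (survival < 0 || survival >= 1)
    stop("survival must be in [0, 1)")
  alpha + survival / (1 - survival)
}

#' Construct a Calibration
#'
#' `G` is computed from `alpha` and `survival` when not supplied.
#'
#' @param muSiteYear mutation rate, substitutions/site/year (may be `NA`
#'   before [calibrateMu()]).
#' @param alpha,survival see [generationTime()].
#' @param G generation time in years (overrides `alpha`/`survival`).
#' @param L total locus length in bp.
#' @param anchorTimeYears,anchorTScaled anchor divergence in years and in
#'   model time units.
#' @return a [Calibration-class].
#' @export
Calibration <- function(muSiteYear = NA_real_, alpha = NA_real_,
                        survival = NA_real_, G = NULL, L = NA_real_,
                        anchorTimeYears = NA_real_,
                        anchorTScaled = NA_real_) {
  if (is.null(G)) {
    G <- if (!is.na(alpha) && !is.na(survival))
      generationTime(alpha, survival) else NA_real_
  }
  new("Calibration", muSiteYear = muSiteYear, G = G, alpha = alpha,
      survival = survival, L = L, anchorTimeYears = anchorTimeYears,
      anchorTScaled = anchorTScaled)
}

setMethod("show", "Calibration", function(object) {
  cat(sprintf(paste0("Calibration: mu = %s /site/year, G = %s y ",
                     "(alpha = %s, survival = %s), L = %s bp\n"),
              format(object@muSiteYear), format(object@G),
              format(object@alpha), format(object@survival),
              format(object@L)))
  if (!is.na(object@anchorTimeYears))
    cat(sprintf("  anchor: %g years at scaled time %g\n",
                object@anchorTimeYears, object@anchorTScaled))
})

#' Calibrate the mutation rate from an anchored divergence time
#'
#' Solves the coupled scaling relations `N_ANC = theta / (4 mu_gen L)` and
#' `anchorTimeYears = anchorTScaled * 2 * N_ANC * G`, which give the
#' closed form
#'
#'   `mu_gen = anchorTScaled * theta * G / (2 * L * anchorTimeYears)`
#'
#' returned per year as `mu_gen / G`.  All intermediates are attached as
#' attribute `"log"` so the provenance of the constant is auditable.
#'
#' @param anchorTimeYears independently estimated divergence time, years.
#' @param anchorTScaled the same divergence on the model's scaled time
#'   axis.
#' @param theta fitted population-scaled mutation rate.
#' @param L locus length in bp.
#' @param G generation time in years.
#' @return mutation rate in substitutions/site/year.
#' @export
calibrateMu <- function(anchorTimeYears, anchorTScaled, theta, L, G) {
  vals <- c(anchorTimeYears, anchorTScaled, theta, L, G)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all calibration inputs must be positive and finite")
  muGen <- anchorTScaled * theta * G / (2 * L * anchorTimeYears)
  mu <- muGen / G
  attr(mu, "log") <- list(muGen = muGen,
                          nAnc = theta / (4 * muGen * L),
                          yearsPerScaledUnit = anchorTimeYears /
                            anchorTScaled)
  mu
}

.muGen <- function(calib) {
  if (is.na(calib@muSiteYear) || is.na(calib@G) || is.na(calib@L))
    stop("calibration is missing muSiteYear, G or L")
  calib@muSiteYear * calib@G
}

#' Ancestral size implied by theta, and its inverse
#'
#' `theta = 4 * N_ANC * mu_gen * L` for diploid autosomal data.
#'
#' @param theta population-scaled mutation rate.
#' @param calib a complete [Calibration-class].
#' @return `nancFromTheta`: ancestral effective size in individuals;
#'   `thetaFromNanc`: theta.
#' @export
nancFromTheta <- function(theta, calib) theta / (4 * .muGen(calib) * calib@L)

#' @rdname nancFromTheta
#' @param nanc ancestral effective size in individuals.
#' @export
thetaFromNanc <- function(nanc, calib) 4 * nanc * .muGen(calib) * calib@L

#' Mutation rate per locus per generation
#'
#' @param muSiteYear substitutions/site/year.
#' @param L locus length in bp.
#' @param G generation time in years.
#' @return substitutions per locus per generation (`mu * G * L`).
#' @export
perLocusRate <- function(muSiteYear, L, G) muSiteYear * G * L

#' Convert a fit to biological units
#'
#' Applies `N_ANC = theta / (4 mu_gen L)`; sizes become
#' `v_k * N_ANC` individuals, durations `t_k * 2 * N_ANC * G` years, and
#' the fitted trajectory is emitted as (years before present, Ne) by
#' cumulative summation backwards from the present.  Multiplicative CIs on
#' the parameters propagate directly onto the sizes.
#'
#' @param fit a converged [FitResult-class].
#' @param calib a complete [Calibration-class].
#' @return an object of class `ScaledDemography`: a list with `nAnc`,
#'   `yearsPerScaled`, a `trajectory` data.frame (`yearsAgoStart`,
#'   `yearsAgoEnd`, `Ne`), scaled `params` with CIs, and the inputs
#'   echoed in `provenance`.
#' @export
scaleFit <- function(fit, calib) {
  stopifnot(is(fit, "FitResult"), is(calib, "Calibration"))
  nAnc <- nancFromTheta(fit@theta, calib)
  yearsPerScaled <- 2 * nAnc * calib@G
  params <- data.frame(param = names(fit@params), scaled = fit@params,
                       row.names = NULL)
  isV <- grepl("^(v|nu)", params$param)
  params$natural <- ifelse(isV, params$scaled * nAnc,
                           params$scaled * yearsPerScaled)
  params$unit <- ifelse(isV, "individuals", "years")
  if (all(params$param %in% rownames(fit@ci))) {
    mult <- ifelse(isV, nAnc, yearsPerScaled)
    params$lower <- fit@ci[params$param, "lower"] * mult
    params$upper <- fit@ci[params$param, "upper"] * mult
  }
  traj <- NULL
  if (!is.null(fit@epochModel)) {
    tr <- fitTrajectory(fit)
    traj <- data.frame(yearsAgoStart = tr$tStart * yearsPerScaled,
                       yearsAgoEnd = tr$tEnd * yearsPerScaled,
                       Ne = tr$v * nAnc)
  }
  structure(list(nAnc = nAnc, yearsPerScaled = yearsPerScaled,
                 params = params, trajectory = traj, theta = fit@theta,
                 provenance = list(muSiteYear = calib@muSiteYear,
                                   G = calib@G, L = calib@L,
                                   scaling = "theta = 4 N_ANC mu_gen L; t in 2 N_ANC generations")),
            class = "ScaledDemography")
}

#' @export
print.ScaledDemography <- function(x, ...) {
  cat(sprintf("ScaledDemography: N_ANC = %.6g individuals, 1 scaled time unit = %.6g years\n",
              x$nAnc, x$yearsPerScaled))
  if (!is.null(x$trajectory))
    cat(sprintf("  trajectory: %d steps, present-day Ne = %.6g\n",
                nrow(x$trajectory), x$trajectory$Ne[nrow(x$trajectory)]))
  invisible(x)
}

#' Invert [scaleFit()]
#'
#' @param scaled a `ScaledDemography`.
#' @param calib the same [Calibration-class] used to scale.
#' @return list with `theta` and the scaled parameter vector, recovered
#'   from the biological-unit values.
#' @export
unscaleFit <- function(scaled, calib) {
  nAnc <- scaled$nAnc
  theta <- thetaFromNanc(nAnc, calib)
  yearsPerScaled <- 2 * nAnc * calib@G
  isV <- grepl("^(v|nu)", scaled$params$param)
  params <- ifelse(isV, scaled$params$natural / nAnc,
                   scaled$params$natural / yearsPerScaled)
  list(theta = theta, params = setNames(params, scaled$params$param))
}
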