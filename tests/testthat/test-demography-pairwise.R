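test_that("the panmictic expectation is exact, symmetric and consistent", {
  ex <- expectedSfs2d("neutral_no_divergence", numeric(), 6, 6)
  m <- sfsEntries(ex)
  expect_equal(m, t(m), tolerance = 1e-12)         # exchange symmetry
  # marginalizing over one population recovers the 1D expectation
  xi <- sfsEntries(expectedSfsStepwise(EpochModel(v = 1, t = 0.1), 12))
  marg <- vapply(1:11, function(b) {
    i <- 0:6; j <- b - i
    ok <- j >= 0 & j <= 6
    sum(m[cbind(i[ok] + 1, j[ok] + 1)])
  }, 0)
  expect_equal(marg, xi[2:12], tolerance = 1e-10)
  # invariance to how samples are split into pseudo-populations: a 4+8
  # split of the same 12 copies has the same total per frequency class
  ex2 <- expectedSfs2d("neutral_no_divergence", numeric(), 4, 8)
  m2 <- sfsEntries(ex2)
  marg2 <- vapply(1:11, function(b) {
    i <- 0:4; j <- b - i
    ok <- j >= 0 & j <= 8
    sum(m2[cbind(i[ok] + 1, j[ok] + 1)])
  }, 0)
  expect_equal(marg2, marg, tolerance = 1e-10)
})

test_that("IM with equal migration nests the symmetric split model", {
  a <- expectedSfs2d("split_migration", c(1, 2, 0.5, 0.8), 5, 5,
                     reps = 5000, seed = 3)
  b <- expectedSfs2d("isolation_with_migration", c(1, 2, 0.5, 0.8, 0.8),
                     5, 5, reps = 5000, seed = 3)
  expect_identical(sfsEntries(a), sfsEntries(b))  # same process, same seed
  expect_error(expectedSfs2d("split_migration", c(1, 2, 0.5), 5, 5),
               "expects 4")
})

test_that("shared-polymorphism mass vanishes for deep no-migration splits", {
  mass <- vapply(c(0.5, 2, 5), function(Tsplit) {
    ex <- expectedSfs2d("split_migration", c(1, 1, Tsplit, 1e-9), 6, 6,
                        reps = 8000, seed = 4)
    m <- sfsEntries(ex)
    sum(m[2:6, 2:6]) / sum(m[2:36])
  }, 0)
  expect_true(all(diff(mass) < 0))
  expect_lt(mass[3], 0.02)
})

test_that("model selection ranks by AIC with a fewer-parameter tie-break", {
  mk <- function(name, ll, params = numeric()) {
    new("FitResult", modelName = name, params = params, theta = 1,
        loglik = ll, se = numeric(), ci = matrix(numeric(), 0, 2),
        epochModel = NULL, nStarts = 1L,
        starts = data.frame(start = 1L, loglik = ll, convergence = 0L),
        converged = TRUE, seed = 1L,
        obsSummary = list(n = c(8L, 8L), checksum = 42))
  }
  # SM gains 20 log-likelihood units for 4 parameters: AIC prefers it
  r <- selectModel(list(mk("neutral_no_divergence", -520),
                        mk("split_migration", -500,
                           c(nu1 = 1, nu2 = 1, T = 1, m = 1))))
  expect_equal(r$model[1], "split_migration")
  expect_equal(r$dAIC, c(0, 32))   # 1040 vs 1008
  # identical log-likelihoods: the model with fewer parameters wins
  r2 <- selectModel(list(mk("neutral_no_divergence", -500),
                         mk("split_migration", -500,
                            c(nu1 = 1, nu2 = 1, T = 1, m = 1))))
  expect_equal(r2$model[1], "neutral_no_divergence")  # tie -> fewer params
  expect_equal(r2$dAIC, c(0, 8))
  bad <- mk("split_no_migration", -490)
  bad@obsSummary$checksum <- 43
  expect_error(selectModel(list(mk("neutral_no_divergence", -1), bad)),
               "different observed")
})

test_that("migration conversions follow the adopted convention", {
  fit <- new("FitResult", modelName = "split_migration",
             params = c(nu1 = 2, nu2 = 0.5, T = 1, m = 1), theta = 1,
             loglik = -1, se = numeric(), ci = matrix(numeric(), 0, 2),
             epochModel = NULL, nStarts = 1L,
             starts = data.frame(), converged = TRUE, seed = 1L,
             obsSummary = list())
  expect_equal(migrantsPerGeneration(fit, 1), 1 * 2 / 2)   # m nu / 2
  expect_equal(migrantsPerGeneration(fit, 2), 1 * 0.5 / 2)
  # m = 0 and no-migration models give exactly zero
  fit@params <- c(nu1 = 2, nu2 = 0.5, T = 1, m = 0)
  expect_equal(migrantsPerGeneration(fit, 1), 0)
  fit@modelName <- "neutral_no_divergence"; fit@params <- numeric()
  expect_equal(migrantsPerGeneration(fit, 1), 0)
  # round trip to machine precision
  M <- migrantsPerGeneration(new("FitResult",
                                 modelName = "isolation_with_migration",
                                 params = c(nu1 = 1.7, nu2 = 1, T = 1,
                                            m12 = 0.37, m21 = 2),
                                 theta = 1, loglik = -1, se = numeric(),
                                 ci = matrix(numeric(), 0, 2),
                                 epochModel = NULL, nStarts = 1L,
                                 starts = data.frame(), converged = TRUE,
                                 seed = 1L, obsSummary = list()), 1)
  expect_equal(scaledMigrationRate(M, 1.7), 0.37, tolerance = 1e-15)
})

test_that("fixing the migration bound at zero reduces to a clean split", {
  obs <- simulateSfs2d(8, 8, "split_no_migration", c(1, 1, 1), theta = 0.2,
                       reps = 4000, seed = 9, aggregate = "sum")
  obs <- applyMask(fold(obs))
  f <- fitPairwise(obs, "split_migration", nStarts = 2, seed = 1,
                   fitReps = 400, polish = FALSE, evalReps = 5000,
                   computeCi = FALSE,
                   bounds = list(nu = c(1e-2, 1e2), T = c(1e-3, 5),
                                 m = c(0, 0)))
  expect_false("m" %in% names(f@params))
  expect_equal(length(f@params), 3L)
})

test_that("pairwise fits recover split-with-migration parameters", {
  # median over replicate datasets: single-replicate maximum-likelihood
  # estimates scatter with the data, the aggregate recovers the truth
  truth <- c(nu1 = 1, nu2 = 1, T = 0.5, m = 0.5)
  pars <- t(vapply(1:5, function(r) {
    obs <- fold(simulateSfs2d(20, 20, "split_migration", truth,
                              theta = 0.2, reps = 12000, seed = 70 + r,
                              aggregate = "sum"))
    fitPairwise(obs, "split_migration", nStarts = 6, seed = r,
                fitReps = 800, polishReps = 8000, evalReps = 3e4,
                computeCi = FALSE)@params
  }, numeric(4)))
  med <- apply(pars, 2, median)
  expect_true(all(abs(med / truth - 1) <= 0.25))
})

test_that("duplicated joint data shrinks pairwise SEs by sqrt(2)", {
  obs <- simulateSfs2d(8, 8, "split_migration", c(1, 1, 0.5, 1),
                       theta = 0.3, reps = 4000, seed = 81,
                       aggregate = "sum")
  obs <- applyMask(fold(obs))
  fit <- fitPairwise(obs, "split_migration", nStarts = 2, seed = 2,
                     fitReps = 400, polish = FALSE, evalReps = 10000,
                     hessianReps = 4000)
  doubled <- Sfs2D(2 * sfsEntries(obs), folded = TRUE, mask = sfsMask(obs))
  fit2 <- fit
  fit2@theta <- 2 * fit@theta
  fit2@obsSummary$checksum <- coalstep:::.obsSummary(doubled)$checksum
  fit2 <- confidenceIntervals(fit2, doubled)
  ok <- is.finite(fit@se) & fit@se > 0
  expect_equal(unname(fit2@se[ok] / fit@se[ok]),
               rep(1 / sqrt(2), sum(ok)), tolerance = 0.05)
})
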