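.pipelineStages <- c("simulate", "filter", "sex", "stats", "sfs",
                     "fit_single", "fit_pairwise", "convert")

## deterministic per-stage seed fan-out from the global seed
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 9973) %% 2147483647)
}

.knownConfigKeys <- c("input", "popMap", "filters", "hweAlpha",
                      "zChromosomes", "sfs", "fitSingle", "fitPairwise",
                      "calibration", "seed", "outDir")

.validateConfig <- function(config) {
  unknown <- setdiff(names(config), .knownConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$filters)) config$filters <- list()
  if (is.null(config$sfs)) config$sfs <- list()
  if (is.null(config$fitSingle)) config$fitSingle <- list()
  config
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - simulate/load, filter, sex, diversity
#' statistics, SFS construction, single-population fit (optionally a
#' pairwise fit), unit conversion - writing every artifact plus a manifest
#' JSON with md5 checksums, the per-stage seeds and the parameters
#' actually used.  When `calibration` is absent the conversion stage is
#' skipped with an explicit notice; the fits are still produced.  Reruns
#' with the same config reproduce identical outputs for the deterministic
#' stages.
#'
#' @param config a named list (or path to a YAML file) with keys among:
#'   `input` (a VCF path, or a list of [StudyDesign()] arguments under
#'   `simulate`), `popMap` (path to a TSV `sampleId<TAB>population`, or a
#'   named vector; defaults to the simulated groups), `filters`
#'   (`minAlleleDepth`, `minPhred`, `minPresence`), `hweAlpha`,
#'   `zChromosomes`, `sfs` (`projectionN`, `maskRule`), `fitSingle`
#'   (`groups`, `nFreeSizes`, `nSteps`, `nStarts`), `fitPairwise`
#'   (`models`, `nStarts`, `fitReps`, `evalReps`, `projectionN`),
#'   `calibration` (arguments of [Calibration()]), `seed`, `outDir`.
#'   Unknown keys are rejected.
#' @param outDir output directory (overrides `config$outDir`).
#' @return the manifest, invisibly (also written to
#'   `<outDir>/manifest.json`).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- .validateConfig(config)
  outDir <- outDir %||% config$outDir %||% stop("no output directory given")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(package = "coalstep",
                   version = as.character(packageVersion("coalstep")),
                   seed = seed, stages = list(), outputs = list(),
                   notices = character())
  addOutput <- function(name, path) {
    manifest$outputs[[name]] <<- list(path = basename(path),
                                      md5 = unname(tools::md5sum(path)))
  }
  note <- function(msg) manifest$notices <<- c(manifest$notices, msg)

  ## stage: input ------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input$simulate)) {
    args <- config$input$simulate
    args$seed <- .stageSeed(seed, "simulate")
    design <- do.call(StudyDesign, args)
    sim <- simulateGenotypeMatrix(design)
    gm <- sim$genotypes
    truth <- sim$truth
    truthPath <- file.path(outDir, "truth.tsv")
    writeSimTruth(truth, truthPath)
    addOutput("truth", truthPath)
    manifest$stages$simulate <- c(args, list(stage_seed = args$seed))
  } else if (!is.null(config$input) && is.character(config$input)) {
    gm <- readGenotypeVcf(config$input)
    manifest$stages$simulate <- list(input = config$input)
  } else stop("config$input must be a VCF path or list(simulate = ...)")

  popMap <- if (!is.null(config$popMap)) {
    if (is.character(config$popMap) && length(config$popMap) == 1L &&
        file.exists(config$popMap)) {
      pm <- read.table(config$popMap, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      setNames(pm[[2]], pm[[1]])
    } else config$popMap
  } else if (!is.null(truth)) truth@group
  else stop("popMap required when input is a VCF")

  ## stage: filter ------------------------------------------------------
  f <- config$filters
  fl <- filterSites(gm,
                    minAlleleDepth = f$minAlleleDepth %||% 5,
                    minPhred = f$minPhred %||% 30,
                    minPresence = f$minPresence %||% 0.8)
  gmF <- extractBiallelicSnps(fl$genotypes)
  hw <- hweScreen(gmF, popMap, alpha = config$hweAlpha %||% 1e-6)
  reportPath <- file.path(outDir, "filter_report.tsv")
  write.table(rbind(fl$report, hw$report), reportPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  addOutput("filter_report", reportPath)
  vcfPath <- file.path(outDir, "filtered.vcf.gz")
  writeGenotypeVcf(gmF, vcfPath)
  addOutput("filtered_vcf", vcfPath)
  manifest$stages$filter <- list(minAlleleDepth = f$minAlleleDepth %||% 5,
                                 minPhred = f$minPhred %||% 30,
                                 minPresence = f$minPresence %||% 0.8,
                                 hweAlpha = config$hweAlpha %||% 1e-6,
                                 sitesIn = nrow(gm), sitesOut = nrow(gmF),
                                 hweFlagged = sum(hw$flagged))

  ## stage: sex ---------------------------------------------------------
  zChrom <- config$zChromosomes %||% "chrZ"
  chroms <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(gmF)))
  if (any(chroms %in% zChrom) && !all(chroms %in% zChrom)) {
    sx <- assignSex(gmF, zChromosomes = zChrom)
    sexPath <- file.path(outDir, "sex_calls.tsv")
    write.table(sx, sexPath, sep = "\t", quote = FALSE, row.names = FALSE)
    addOutput("sex_calls", sexPath)
    manifest$stages$sex <- list(zChromosomes = zChrom,
                                called = sum(sx$call != "unassigned"))
  } else note("sex stage skipped: no Z-linked (or no autosomal) sites")

  ## stage: stats -------------------------------------------------------
  aut <- gmF[!(chroms %in% zChrom), ]
  pops <- unique(unname(popMap[colnames(aut)]))
  piTab <- do.call(rbind, lapply(pops, function(p) {
    d <- nucleotideDiversity(aut,
                             populations = colnames(aut)[popMap[colnames(aut)] == p])
    d$population <- p
    d
  }))
  phiTab <- NULL
  if (length(pops) >= 2L) {
    prs <- utils::combn(pops, 2L, simplify = FALSE)
    phiTab <- do.call(rbind, lapply(prs, function(pr) {
      res <- phiSt(aut, popMap[colnames(aut)], pair = pr)
      data.frame(pop1 = pr[1], pop2 = pr[2], compositePhiSt = res$composite)
    }))
  }
  statsPath <- file.path(outDir, "diversity.tsv")
  write.table(piTab, statsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  addOutput("diversity", statsPath)
  if (!is.null(phiTab)) {
    phiPath <- file.path(outDir, "phi_st.tsv")
    write.table(phiTab, phiPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addOutput("phi_st", phiPath)
  }
  manifest$stages$stats <- list(populations = pops)

  ## stage: sfs + single-population fits --------------------------------
  sfsCfg <- config$sfs
  fitCfg <- config$fitSingle
  fitGroups <- fitCfg$groups %||% pops
  fits <- list()
  for (p in fitGroups) {
    ids <- colnames(aut)[popMap[colnames(aut)] == p]
    sf <- buildSfs1d(aut, samples = ids,
                     projectionN = sfsCfg$projectionN)
    sf <- applyMask(fold(sf), sfsCfg$maskRule %||% "singletons_and_full")
    sfsPath <- file.path(outDir, paste0("sfs_", p, ".fs"))
    writeSfs(sf, sfsPath)
    addOutput(paste0("sfs_", p), sfsPath)
    fit <- fitStepwise(sf,
                       nFreeSizes = fitCfg$nFreeSizes %||% 10L,
                       nSteps = fitCfg$nSteps %||% 100L,
                       nStarts = fitCfg$nStarts %||% 50L,
                       seed = .stageSeed(seed, paste0("fit_single_", p)))
    fits[[p]] <- fit
    fitPath <- file.path(outDir, paste0("fit_", p, ".json"))
    .writeJson(list(model = fit@modelName, params = as.list(fit@params),
                    theta = fit@theta, loglik = fit@loglik,
                    se = as.list(fit@se), nStarts = fit@nStarts,
                    seed = fit@seed,
                    timeUnits = "sizes x N_ANC; durations in 2 N_ANC generations",
                    trajectory = fitTrajectory(fit)), fitPath)
    addOutput(paste0("fit_", p), fitPath)
    trajPath <- file.path(outDir, paste0("trajectory_", p, ".tsv"))
    write.table(fitTrajectory(fit), trajPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addOutput(paste0("trajectory_", p), trajPath)
  }
  manifest$stages$fit_single <- list(groups = fitGroups,
                                     nFreeSizes = fitCfg$nFreeSizes %||% 10L,
                                     nSteps = fitCfg$nSteps %||% 100L,
                                     nStarts = fitCfg$nStarts %||% 50L)

  ## stage: pairwise fits (optional) ------------------------------------
  if (!is.null(config$fitPairwise)) {
    pc <- config$fitPairwise
    pr <- pc$pair %||% pops[1:2]
    ids1 <- colnames(aut)[popMap[colnames(aut)] == pr[1]]
    ids2 <- colnames(aut)[popMap[colnames(aut)] == pr[2]]
    sf2 <- buildSfs2d(aut, ids1, ids2, projectionN = pc$projectionN)
    sf2 <- applyMask(fold(sf2))
    pfits <- lapply(pc$models %||% c("neutral_no_divergence",
                                     "split_migration"),
                    function(mn) fitPairwise(sf2, mn,
                      nStarts = pc$nStarts %||% 5L,
                      fitReps = pc$fitReps %||% 2000L,
                      evalReps = pc$evalReps %||% 20000L,
                      seed = .stageSeed(seed, paste0("fit_pair_", mn))))
    rank <- selectModel(pfits)
    rankPath <- file.path(outDir, "model_selection.tsv")
    write.table(rank, rankPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addOutput("model_selection", rankPath)
    manifest$stages$fit_pairwise <- list(pair = pr, best = rank$model[1])
  }

  ## stage: conversion --------------------------------------------------
  if (!is.null(config$calibration)) {
    calib <- do.call(Calibration, config$calibration)
    conv <- lapply(names(fits), function(p) {
      sc <- scaleFit(fits[[p]], calib)
      data.frame(population = p, yearsAgoStart = sc$trajectory$yearsAgoStart,
                 yearsAgoEnd = sc$trajectory$yearsAgoEnd,
                 Ne = sc$trajectory$Ne)
    })
    convPath <- file.path(outDir, "ne_trajectories.tsv")
    write.table(do.call(rbind, conv), convPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addOutput("ne_trajectories", convPath)
    manifest$stages$convert <- config$calibration
  } else {
    note("conversion stage skipped: no calibration block in config")
  }

  manifestPath <- file.path(outDir, "manifest.json")
  .writeJson(manifest, manifestPath)
  invisible(manifest)
}

#' Build the packaged demo cohort
#'
#' Simulates a small three-group cohort (12 samples per group, 2000
#' autosomal + 200 Z-linked sites) with truth, writes it under `dir` as
#' VCF + truth TSV + population map, and returns the paths with
#' checksums.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return list of paths and md5 checksums.
#' @export
makeFixture <- function(seed = 42L, dir = tempfile("coalstep_fixture")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- StudyDesign(nSamplesPerGroup = 12L, nAutosomalSites = 2000L,
                        nZSites = 200L, nGroups = 3L, missingRate = 0.05,
                        seed = seed)
  sim <- simulateGenotypeMatrix(design)
  vcf <- file.path(dir, "cohort.vcf.gz")
  writeGenotypeVcf(sim$genotypes, vcf)
  truth <- file.path(dir, "truth.tsv")
  writeSimTruth(sim$truth, truth)
  pop <- file.path(dir, "popmap.tsv")
  write.table(data.frame(sampleId = names(sim$truth@group),
                         population = sim$truth@group),
              pop, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf, truth = truth, popmap = pop)
  list(dir = dir, paths = paths, md5 = tools::md5sum(paths))
}
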