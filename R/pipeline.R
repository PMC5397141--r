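#' Run the full CpCpG coupling analysis end to end
#'
#' Orchestrates every stage of the analysis over a set of methylomes and
#' writes all results, plus a run manifest, to an output directory. The
#' input is either a [SimulationConfig-class] (the methylomes are then
#' simulated, and the planted truth is written alongside) or a list with
#' `genome` (FASTA path or sequences) and `samples` (named list of Bismark
#' CX report paths, which must include `wt`). Stages: cytosine annotation
#' and CpCpG pairing; coverage and WT-methylation filters; per-context
#' mutant contrasts; CpCpG pattern frequencies; CDC/RDC dependency calls
#' (when a cmt2/3 sample is present); internal/external correlation (when
#' a met1-1 sample is present); DMB calling per context and mutant; tile
#' classification, CpCpG-based IBM1-target prediction and spreading
#' profiles with decay fit (when an ibm1 sample is present). Stages whose
#' input sample is absent are skipped with a logged reason. Outputs are
#' deterministic: running twice with the same config yields byte-identical
#' files.
#'
#' @param config A [SimulationConfig-class], or a list with elements
#'   `genome` and `samples` as described above.
#' @param outDir Output directory (created if needed).
#' @param mutants Mutants to simulate when `config` is a
#'   [SimulationConfig-class] (default all five).
#' @param minReads Coverage filter threshold (default 5).
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
runPipeline <- function(config, outDir,
                        mutants = c("met1-3", "met1-1", "cmt2-3", "ddcc",
                                    "ibm1"),
                        minReads = 5) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stageCounts <- list()
  note <- function(...) message("[ccgmeth] ", ...)

  if (is(config, "SimulationConfig")) {
    note("simulating methylomes (seed ", config@seed, ")")
    sim <- simulateMethylomes(config, mutants = mutants)
    anno <- sim$annotations
    ccg <- sim$ccgSites
    profiles <- sim$profiles
    simDir <- file.path(outDir, "simulated")
    dir.create(simDir, showWarnings = FALSE)
    writeXStringSet(sim$genome, file.path(simDir, "genome.fa"))
    for (s in names(profiles))
      writeCXReport(profiles[[s]], anno,
                    file.path(simDir, paste0(s, ".CX_report.txt")))
    writeTruth(sim, file.path(simDir, "truth"))
    configEcho <- list(type = "simulation", seed = config@seed,
                       chromLengths = as.list(config@chromLengths),
                       coverage = config@coverage,
                       qExt = config@qExt,
                       ibm1Lambda = config@ibm1Lambda,
                       met1Rho = config@met1Rho)
  } else {
    if (!is.list(config) || is.null(config$genome) ||
        is.null(config$samples) || !"wt" %in% names(config$samples))
      stop("'config' must be a SimulationConfig or a list with 'genome' ",
           "and a 'samples' list containing 'wt'")
    missing <- !vapply(unlist(config$samples), file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(config$samples)[missing], collapse = ", "))
    note("annotating genome")
    anno <- annotateCytosines(config$genome)
    ccg <- findCCGSites(anno)
    profiles <- lapply(names(config$samples), function(s)
      readCXReport(config$samples[[s]], sampleId = s))
    names(profiles) <- names(config$samples)
    configEcho <- list(type = "files",
                       samples = lapply(config$samples, normalizePath),
                       digests = lapply(config$samples,
                                        function(p) unname(tools::md5sum(p))))
  }
  stageCounts$nCytosines <- length(anno)
  stageCounts$nCCGSites <- length(ccg)
  writeAnnotationTable(anno, file.path(outDir, "cytosine_annotation.tsv"))
  writeCCGSites(ccg, file.path(outDir, "ccg_sites.tsv"))
  utils::write.table(contextCensus(anno),
                     file.path(outDir, "context_census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  wt <- profiles$wt
  note("coverage filter across ", length(profiles), " samples")
  covSet <- filterMinCoverage(profiles, minReads = minReads)
  wtSet <- filterWTMethylated(wt, covSet, anno)
  stageCounts$nSitesCovered <- length(covSet)
  stageCounts$nSitesWTMethylated <- length(wtSet)

  present <- setdiff(names(profiles), "wt")
  for (m in intersect(c("met1-3", "cmt2-3", "ddcc", "met1-1"), present)) {
    cc <- contextContrast(wt, profiles[[m]], wtSet, anno)
    utils::write.table(cc$summary,
                       file.path(outDir, paste0("contrast_", m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pat <- ccgPattern(wt, ccg)
  utils::write.table(
    data.frame(pattern = names(pat$freq), frequency = pat$freq,
               count = as.integer(pat$counts)),
    file.path(outDir, "ccg_patterns_wt.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  summaryJSON <- list(ccgPatternFreqWT = as.list(pat$freq))

  if ("cmt2-3" %in% present) {
    dep <- classifyCCGDependency(wt, profiles[["cmt2-3"]], ccg)
    utils::write.table(dep, file.path(outDir, "ccg_dependency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaryJSON$dependencyCounts <- as.list(table(dep$label))
    stageCounts$nDependencyClassified <- nrow(dep)
  } else note("no cmt2/3 sample: dependency classification skipped")

  if ("met1-1" %in% present) {
    iec <- internalExternalCorrelation(wt, profiles[["met1-1"]], ccg)
    utils::write.table(iec$pairs,
                       file.path(outDir, "internal_external_deltas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaryJSON$internalExternalSpearman <- iec$rho
  } else note("no met1-1 sample: internal/external correlation skipped")

  for (m in present) {
    for (ctx in c("CG", "CHG", "CHH")) {
      dmbs <- callDMBs(wt, profiles[[m]], anno, ctx)
      df <- data.frame(chrom = as.character(seqnames(dmbs)),
                       start = start(dmbs) - 1L, end = end(dmbs),
                       context = rep(ctx, length(dmbs)),
                       diff = dmbs$diff, z = dmbs$z,
                       p = dmbs$p, nCytosines = dmbs$nCytosines,
                       direction = dmbs$direction)
      utils::write.table(df,
                         file.path(outDir,
                                   paste0("dmbs_", m, "_", ctx, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stageCounts[[paste0("nDMB_", m, "_", ctx)]] <- length(dmbs)
    }
  }

  if ("ibm1" %in% present) {
    ibm1 <- profiles$ibm1
    wtTiles <- tileMethylation(wt, anno, ccg)
    ibm1Tiles <- tileMethylation(ibm1, anno, ccg)
    classes <- classifyTiles(wtTiles, ibm1Tiles)
    pred <- predictIBM1Targets(ibm1Tiles, classes)
    tileDF <- data.frame(
      chrom = as.character(seqnames(wtTiles)),
      start = start(wtTiles) - 1L, end = end(wtTiles),
      wtCG = wtTiles$meanCG, wtCHG = wtTiles$meanCHG,
      wtCHH = wtTiles$meanCHH, ibm1CHG = ibm1Tiles$meanCHG,
      nCCG = ibm1Tiles$nCCG,
      nCCGInternalMeth = ibm1Tiles$nCCGInternalMeth,
      class = classes, predictedTarget = pred$predicted)
    utils::write.table(tileDF, file.path(outDir, "tiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaryJSON$tileClassCounts <- as.list(table(classes))
    summaryJSON$ibm1PredictionPrecision <- pred$precision
    summaryJSON$ibm1PredictionRecall <- pred$recall

    seeds <- selectSeedSites(wt, ibm1, ccg)
    stageCounts$nSeedSites <- length(seeds)
    if (length(seeds)) {
      prof <- distanceProfile(seeds, wt, ibm1, anno)
      utils::write.table(prof, file.path(outDir, "spreading_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit <- tryCatch(suppressWarnings(fitDecay(prof)), error = function(e) NULL)
      if (!is.null(fit))
        summaryJSON$spreadingDecay <- fit[c("amplitude", "lambda")]
      seedDF <- data.frame(chrom = as.character(seqnames(seeds)),
                           start = start(seeds) - 1L, end = end(seeds),
                           strand = as.character(strand(seeds)),
                           isolated = seeds$isolated)
      utils::write.table(seedDF, file.path(outDir, "seed_sites.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else note("no ibm1 sample: tile classification and spreading skipped")

  jsonlite::write_json(summaryJSON, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "ccgmeth",
    version = as.character(utils::packageVersion("ccgmeth")),
    config = configEcho,
    samples = names(profiles),
    stageCounts = stageCounts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
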