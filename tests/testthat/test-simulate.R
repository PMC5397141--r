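test_that("the generator is fully deterministic given the seed", {
  cfg <- simulationConfig(seed = 101, chromLengths = c(chr1 = 30000))
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(GenomicRanges::start(g1$genes),
                   GenomicRanges::start(g2$genes))
  s1 <- simulateMethylomes(cfg, mutants = "ddcc")
  s2 <- simulateMethylomes(cfg, mutants = "ddcc")
  expect_identical(s1$wtState$levels, s2$wtState$levels)
  expect_identical(methReads(s1$profiles$ddcc), methReads(s2$profiles$ddcc))
  ## a different seed changes the genome
  g3 <- generateGenome(simulationConfig(seed = 102,
                                        chromLengths = c(chr1 = 30000)))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("every gene and TE interval contains a usable CpCpG site", {
  cfg <- simulationConfig(seed = 103, chromLengths = c(chr1 = 40000))
  parts <- generateGenome(cfg)
  anno <- annotateCytosines(parts$genome)
  ccg <- findCCGSites(anno)
  ivs <- c(parts$genes, parts$tes)
  expect_true(all(GenomicRanges::countOverlaps(ivs, ccg,
                                               ignore.strand = TRUE) >= 1L))
})

test_that("WT truth obeys the compartment and coupling rules", {
  cfg <- smallSimConfig(seed = 104)
  sim <- simulateMethylomes(cfg, mutants = character(0))
  lev <- sim$wtState$levels
  anno <- sim$annotations
  eps <- 0.01
  ctx <- as.character(anno$context)
  inGene <- IRanges::overlapsAny(anno, sim$genes, ignore.strand = TRUE)
  inTE <- IRanges::overlapsAny(anno, sim$tes, ignore.strand = TRUE)
  ## gene bodies: non-CpG at the noise floor
  expect_true(all(lev[inGene & !inTE & ctx %in% c("CHG", "CHH")] <= eps))
  ## background unmethylated (CpG dyads straddling an interval edge share
  ## the interval's level across the boundary, so allow a 1-bp margin)
  nearIv <- IRanges::overlapsAny(anno, c(sim$genes, sim$tes), maxgap = 1,
                                 ignore.strand = TRUE)
  expect_true(all(lev[!nearIv] <= eps))
  ## the forbidden external-only pattern never occurs in the truth
  ext <- sim$wtState$extIdx; int <- sim$wtState$intIdx
  expect_equal(sum(lev[ext] >= 0.5 & lev[int] < 0.5), 0L)
  ## among internally methylated TE CpCpGs, externals on at about qExt
  teExt <- IRanges::overlapsAny(anno[ext], sim$tes, ignore.strand = TRUE)
  im <- teExt & lev[int] >= 0.5
  expect_gt(sum(im), 100L)
  expect_equal(mean(lev[ext][im] >= 0.5), cfg@qExt, tolerance = 0.15)
  ## symmetric CpG dyads share one level across strands
  dyad <- sim$wtState$dyadOf
  isCG <- !is.na(dyad)
  expect_true(all(tapply(lev[isCG], dyad[isCG],
                         function(x) diff(range(x))) == 0))
  ## RdDM flags are defined exactly for methylated externals
  expect_identical(is.na(sim$truth$rdmFlag), lev[ext] < 0.5)
})

test_that("mutant rules transform the truth as specified", {
  sim <- simulateMethylomes(smallSimConfig(seed = 105))
  wt <- sim$wtState$levels
  ctx <- as.character(sim$annotations$context)
  ext <- sim$wtState$extIdx
  eps <- 0.01
  ## ddcc: all non-CpG at the floor, CpG untouched
  dd <- sim$mutantStates$ddcc$levels
  expect_true(all(dd[ctx %in% c("CHG", "CHH")] <= eps))
  expect_identical(dd[ctx == "CG"], wt[ctx == "CG"])
  ## met1-3: CpG and CpCpG externals erased, CAG/CTG untouched
  m3 <- sim$mutantStates$`met1-3`$levels
  expect_true(all(m3[ctx == "CG"] <= eps))
  expect_true(all(m3[ext] <= eps))
  sub <- sim$annotations$subcontext
  expect_identical(m3[sub %in% c("CAG", "CTG")],
                   wt[sub %in% c("CAG", "CTG")])
  ## cmt2/3: CDC externals lose >= 99%, RDC externals retain > 20%
  c23 <- sim$mutantStates$`cmt2-3`$levels
  flag <- sim$truth$rdmFlag
  cdc <- which(!is.na(flag) & !flag); rdc <- which(!is.na(flag) & flag)
  expect_true(all(c23[ext[cdc]] <= 0.01 * wt[ext[cdc]]))
  expect_true(all(c23[ext[rdc]] > 0.20 * wt[ext[rdc]]))
  ## ibm1: CpG untouched; gains restricted to planted target genes
  ib <- sim$mutantStates$ibm1$levels
  expect_identical(ib[ctx == "CG"], wt[ctx == "CG"])
  gained <- which(ib - wt > 0.01)
  expect_gt(length(gained), 0L)
  expect_true(all(ctx[gained] == "CHG"))
  expect_true(all(IRanges::overlapsAny(sim$annotations[gained],
                                       sim$truth$targetGenes,
                                       ignore.strand = TRUE)))
  ## and never at CpCpG externals with unmethylated internals
  int <- sim$wtState$intIdx
  blocked <- ext[wt[int] < 0.5]
  expect_true(all(abs(ib[blocked] - wt[blocked]) < 1e-12))
  expect_error(deriveMutantState(sim$wtState, "nonsense"), "unknown mutant")
})

test_that("read sampling respects coverage and truth extremes", {
  cfg <- simulationConfig(seed = 106, chromLengths = c(chr1 = 20000))
  parts <- generateGenome(cfg)
  anno <- annotateCytosines(parts$genome)
  n <- length(anno)
  ## zero coverage: all totals zero
  p0 <- sampleReads(rep(0.5, n), anno, cfg, 1, coverage = 0)
  expect_true(all(totalReads(p0) == 0L))
  ## true level 1: methylated equals total everywhere
  p1 <- sampleReads(rep(1, n), anno, cfg, 2, coverage = 20)
  expect_identical(methReads(p1), totalReads(p1))
  ## at 50x the empirical level tracks the truth within the binomial bound
  set.seed(3)
  truth <- runif(n)
  p50 <- sampleReads(truth, anno, cfg, 4, coverage = 50)
  lev <- methLevel(p50)
  ok <- !is.na(lev)
  expect_lt(mean(abs(lev[ok] - truth[ok])), 0.08)
  ## negative-binomial coverage is supported
  cfgNB <- simulationConfig(seed = 106, chromLengths = c(chr1 = 20000),
                            dispersion = 2)
  pnb <- sampleReads(truth, anno, cfgNB, 5, coverage = 20)
  expect_gt(stats::var(as.numeric(totalReads(pnb))), 20 * 1.5)
})

test_that("truth files are written and re-emitted deterministically", {
  sim <- simulateMethylomes(
    simulationConfig(seed = 107, chromLengths = c(chr1 = 20000)),
    mutants = c("ddcc", "ibm1"))
  d1 <- file.path(tempdir(), "truth1"); d2 <- file.path(tempdir(), "truth2")
  writeTruth(sim, d1)
  writeTruth(sim, d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_setequal(basename(f1),
                  c("true_levels.tsv", "ccg_truth.tsv", "target_tiles.bed",
                    "params.json"))
  h1 <- tools::md5sum(sort(f1))
  h2 <- tools::md5sum(sort(list.files(d2, full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))
  ## CDC/RDC flags partition the methylated externals
  ccg <- read.delim(file.path(d1, "ccg_truth.tsv"))
  expect_true(all(ccg$dependency[ccg$externalMethylated] %in%
                    c("CDC", "RDC")))
  expect_true(all(ccg$dependency[!ccg$externalMethylated] == "none"))
  ## planted target tiles lie inside gene intervals
  bed <- read.delim(file.path(d1, "target_tiles.bed"), header = FALSE)
  tt <- GenomicRanges::GRanges(bed$V1, IRanges::IRanges(bed$V2 + 1L, bed$V3))
  expect_true(all(IRanges::overlapsAny(tt, sim$genes)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(qExt = 1.5), "probabilities")
  expect_error(simulationConfig(ibm1Lambda = -10), "positive")
  expect_error(simulationConfig(chromLengths = c(chr1 = 20001)),
               "multiples of tileWidth")
  expect_error(simulationConfig(geneFraction = 0.8, teFraction = 0.5),
               "not exceed 1")
})
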