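test_that("tile means are means of per-cytosine levels over covered sites", {
  genome <- c(chr1 = paste(c(rep("TTCGATTCAGTT", 20), rep("A", 260)),
                           collapse = ""))
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  ## plus-strand CG sites at 0.8/0.6/1.0 pattern, everything else uncovered
  ctx <- as.character(anno$context)
  str <- as.character(GenomicRanges::strand(anno))
  isCG <- ctx == "CG" & str == "+"
  lev <- rep(0, length(anno))
  lev[isCG] <- rep_len(c(0.8, 0.6, 1.0), sum(isCG))
  tot <- ifelse(isCG, 10L, 0L)
  p <- MethylationProfile(GenomicRanges::GRanges(
    GenomicRanges::seqnames(anno),
    IRanges::IRanges(GenomicRanges::start(anno), width = 1L),
    strand = GenomicRanges::strand(anno)),
    meth = as.integer(round(lev * tot)), total = tot)
  tiles <- tileMethylation(p, anno, ccg)
  expect_equal(tiles$meanCG[1], mean(rep_len(c(0.8, 0.6, 1.0), sum(isCG))))
  ## contexts without coverage carry NA means
  expect_true(is.na(tiles$meanCHH[1]))
  expect_true(is.na(tiles$meanCHG[1]))
})

test_that("CpCpG status per tile counts methylated internals", {
  genome <- c(chr1 = paste(c(rep("ACCGTTT", 3), rep("A", 479)),
                           collapse = ""))
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  expect_length(ccg, 3L)
  p <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+",
                   c(0, 0, 0, 0.9, 0.8, 0.1))
  tiles <- tileMethylation(p, anno, ccg)
  st <- ccgStatusPerTile(tiles)
  expect_equal(st$nCCG[1], 3L)
  expect_equal(st$nCCGInternalMeth[1], 2L)
  expect_equal(st$fracInternalMeth[1], 2 / 3)
  ## a tile without CpCpG sites has an undefined fraction
  expect_true(all(st$nCCG[-1] == 0L))
  expect_true(all(is.na(st$fracInternalMeth[-1])))
})

test_that("tile classification follows the rule cascade", {
  mk <- function(cg, chg, chh, nInt = 0L) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
      meanCG = cg, meanCHG = chg, meanCHH = chh, nCCG = 3L,
      nCCGInternalMeth = nInt, fracInternalMeth = nInt / 3)
    gr
  }
  ## gbM tile gaining 0.53 CHG -> target
  expect_equal(as.character(classifyTiles(mk(0.15, 0.02, 0.01),
                                          mk(0.15, 0.55, 0.01))),
               "gbM_IBM1_target")
  ## same WT, ibm1 CHG 0.04 -> independent
  expect_equal(as.character(classifyTiles(mk(0.15, 0.02, 0.01),
                                          mk(0.15, 0.04, 0.01))),
               "gbM_IBM1_independent")
  ## WT CHG 0.6 -> TE regardless of ibm1
  expect_equal(as.character(classifyTiles(mk(0.15, 0.60, 0.01),
                                          mk(0.15, 0.90, 0.01))), "TE")
  ## intermediate gain stays unassigned
  expect_equal(as.character(classifyTiles(mk(0.15, 0.02, 0.01),
                                          mk(0.15, 0.20, 0.01))), "other")
  ## undefined means are unclassifiable
  expect_equal(as.character(classifyTiles(mk(NA_real_, 0.02, 0.01),
                                          mk(0.15, 0.55, 0.01))), "other")
})

test_that("every tile receives exactly one class and the rule is monotone", {
  sim <- simulateMethylomes(smallSimConfig(seed = 81, coverage = 20),
                            mutants = "ibm1")
  wtT <- tileMethylation(sim$profiles$wt, sim$annotations, sim$ccgSites)
  ibT <- tileMethylation(sim$profiles$ibm1, sim$annotations, sim$ccgSites)
  cl <- classifyTiles(wtT, ibT)
  expect_false(anyNA(cl))
  expect_equal(sum(table(cl)), length(wtT))
  nTargets <- vapply(c(0.2, 0.4, 0.5, 0.7), function(g)
    sum(classifyTiles(wtT, ibT, targetGainMin = g) == "gbM_IBM1_target"),
    numeric(1))
  expect_true(all(diff(nTargets) <= 0))
})

test_that("internally methylated CpCpGs predict planted IBM1 targets", {
  sim <- simulateMethylomes(smallSimConfig(seed = 82, coverage = 20),
                            mutants = "ibm1")
  ibT <- tileMethylation(sim$profiles$ibm1, sim$annotations, sim$ccgSites)
  tileKey <- paste0(as.character(GenomicRanges::seqnames(ibT)), ":",
                    GenomicRanges::start(ibT))
  plantKey <- paste0(
    as.character(GenomicRanges::seqnames(sim$truth$targetTiles)), ":",
    GenomicRanges::start(sim$truth$targetTiles))
  planted <- tileKey %in% plantKey
  geneTile <- IRanges::overlapsAny(ibT, sim$genes, ignore.strand = TRUE)
  pred <- predictIBM1Targets(ibT, planted, within = geneTile)
  expect_gt(pred$precision, 0.9)
  expect_gt(pred$recall, 0.9)
  ## hand-held cases: 2-of-2 methylated -> target; 0-of-3 -> independent
  expect_true(pred$predicted[which(planted)[1]])
})

test_that("ecotype comparison classifies pairs and rejects bad homology", {
  pairs <- data.frame(
    chgA = c(0.6, 0.02, 0.7, 0.03, 0.3, 0.6),
    chgB = c(0.02, 0.6, 0.8, 0.01, 0.3, 0.6),
    nCCG = c(3, 2, 5, 1, 2, 0),
    nInternalMethA = c(2, 0, 4, 0, 1, 1),
    nInternalMethB = c(0, 3, 4, 0, 1, 1),
    alnLen = c(500, 480, 520, 900, 450, 500))
  cmp <- compareEcotypes(pairs)
  expect_equal(as.character(cmp$pairs$class),
               c("Col_only", "Ler_only", "both", "neither"))
  expect_equal(nrow(cmp$rejected), 2L)
  expect_setequal(cmp$rejected$reason,
                  c("alignment length outside range", "no CpCpG site"))
  ## symmetry under swapping ecotypes
  swapped <- data.frame(
    chgA = pairs$chgB, chgB = pairs$chgA, nCCG = pairs$nCCG,
    nInternalMethA = pairs$nInternalMethB,
    nInternalMethB = pairs$nInternalMethA, alnLen = pairs$alnLen)
  cmpS <- compareEcotypes(swapped)
  map <- c(Col_only = "Ler_only", Ler_only = "Col_only", both = "both",
           neither = "neither")
  expect_equal(as.character(cmpS$pairs$class),
               unname(map[as.character(cmp$pairs$class)]))
})

test_that("two-ecotype simulation reproduces the asymmetric CpCpG signal", {
  eco <- simulateEcotypes(smallSimConfig(seed = 83, coverage = 30))
  cmp <- compareEcotypes(eco$pairs)
  summ <- cmp$summary
  aOnly <- summ[summ$class == "Col_only", ]
  bOnly <- summ[summ$class == "Ler_only", ]
  expect_gt(aOnly$n, 0)
  expect_gt(bOnly$n, 0)
  expect_gt(aOnly$medianInternalMethA, 0)
  expect_equal(aOnly$medianInternalMethB, 0)
  expect_gt(bOnly$medianInternalMethB, 0)
  expect_equal(bOnly$medianInternalMethA, 0)
})
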