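test_that("relative change has the right anchor points", {
  genome <- c(chr1 = "TTCGATTCAGTT")
  anno <- annotateCytosines(genome)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3L, 8L),
                                                           width = 1L),
                                  strand = "+")
  wt <- makeProfile("chr1", c(3L, 8L), "+", c(0.8, 0.8))
  mut <- makeProfile("chr1", c(3L, 8L), "+", c(0.0, 0.8))
  cc <- suppressWarnings(contextContrast(wt, mut, sites, anno))
  expect_equal(cc$perSite$relChange[cc$perSite$class == "CG"], -1)
  expect_equal(cc$perSite$relChange[cc$perSite$class == "CAG"], 0)
  expect_true(all(cc$perSite$relChange >= -1))
})

test_that("met1-3 simulation reproduces the per-context loss signature", {
  sim <- simulateMethylomes(smallSimConfig(seed = 41, coverage = 20),
                            mutants = "met1-3")
  suppressMessages({
    cov <- filterMinCoverage(sim$profiles[c("wt", "met1-3")], 5)
    wtset <- filterWTMethylated(sim$profiles$wt, cov, sim$annotations)
  })
  cc <- contextContrast(sim$profiles$wt, sim$profiles$`met1-3`, wtset,
                        sim$annotations)
  med <- setNames(cc$summary$median, cc$summary$class)
  expect_lt(med[["CG"]], -0.9)
  expect_lt(med[["CCG"]], -0.9)
  expect_lt(abs(med[["CAG"]]), 0.1)
  expect_lt(abs(med[["CTG"]]), 0.1)
})

test_that("CDC/RDC labels follow the fractional thresholds exactly", {
  genome <- c(chr1 = "ACCGTTTACCGTTTACCGTTT")
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  expect_length(ccg, 3L)
  ext <- ccg$externalPos
  wt <- makeProfile("chr1", c(ext, ext + 1L), "+", 0.50, total = 1000L)
  ## mutant external levels: 0.004 (CDC: <= 0.005), 0.15 (RDC: > 0.10),
  ## 0.05 (ambiguous)
  mut <- makeProfile("chr1", c(ext, ext + 1L), "+",
                     c(0.004, 0.15, 0.05, 0.5, 0.5, 0.5), total = 1000L)
  dep <- classifyCCGDependency(wt, mut, ccg)
  expect_equal(as.character(dep$label), c("CDC", "RDC", "ambiguous"))
  ## WT level 0 is unclassifiable
  wt0 <- makeProfile("chr1", c(ext, ext + 1L), "+", 0, total = 1000L)
  expect_equal(nrow(classifyCCGDependency(wt0, mut, ccg)), 0L)
})

test_that("dependency labels recover planted flags on simulated data", {
  sim <- simulateMethylomes(smallSimConfig(seed = 42, coverage = 20),
                            mutants = "cmt2-3")
  dep <- classifyCCGDependency(sim$profiles$wt, sim$profiles$`cmt2-3`,
                               sim$ccgSites)
  flag <- sim$truth$rdmFlag
  key <- paste0(as.character(GenomicRanges::seqnames(sim$ccgSites)), ":",
                sim$ccgSites$externalPos, ":",
                as.character(GenomicRanges::strand(sim$ccgSites)))
  truth <- ifelse(flag, "RDC", "CDC")[match(dep$key, key)]
  ok <- !is.na(truth)
  expect_gt(mean(as.character(dep$label)[ok] == truth[ok]), 0.9)
})

test_that("CpCpG patterns are called per site and frequencies sum to 1", {
  genome <- c(chr1 = "ACCGTTTACCGTTTACCGTTTACCGTTT")
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  ext <- ccg$externalPos
  ## (ext, int) level pairs: MM, UM, UU and one uncovered site
  p <- makeProfile("chr1", c(ext[1:3], ext[1:3] + 1L), "+",
                   c(0.6, 0.1, 0.2, 0.7, 0.7, 0.3))
  pat <- ccgPattern(p, ccg)
  expect_equal(as.character(pat$perSite$pattern), c("MM", "UM", "UU"))
  expect_equal(sum(pat$freq), 1)
  expect_equal(pat$nSkipped, 1L)
  ## order invariance
  pat2 <- ccgPattern(p, rev(ccg))
  expect_equal(sort(as.character(pat2$perSite$pattern)),
               sort(as.character(pat$perSite$pattern)))
  expect_equal(pat2$freq, pat$freq)
})

test_that("the forbidden MU pattern is rarer than MM in simulated WT", {
  sim <- simulateMethylomes(smallSimConfig(seed = 43, coverage = 30),
                            mutants = character(0))
  pat <- ccgPattern(sim$profiles$wt, sim$ccgSites)
  expect_lt(pat$freq[["MU"]], pat$freq[["MM"]])
})

test_that("Spearman agrees with an independent rank-based oracle", {
  ## oracle: Pearson correlation of average ranks
  spearOracle <- function(x, y) {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  genome <- c(chr1 = paste(rep("ACCGTTT", 8), collapse = ""))
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  n <- length(ccg)
  expect_gte(n, 8L)
  set.seed(5)
  wtLev <- rep(0.8, 2L * n)
  mutInt <- round(runif(n, 0, 0.8), 1)   # ties on purpose
  mutExt <- round(runif(n, 0, 0.8), 1)
  wt <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+", wtLev,
                    total = 100L)
  mut <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+",
                     c(mutExt, mutInt), total = 100L)
  iec <- internalExternalCorrelation(wt, mut, ccg)
  expect_equal(iec$n, n)
  expect_equal(iec$rho,
               spearOracle((mutInt - 0.8) / 0.8, (mutExt - 0.8) / 0.8),
               tolerance = 1e-12)
})

test_that("coupled deltas give rho 1 and independent deltas give rho near 0", {
  genome <- c(chr1 = paste(rep("ACCGTTT", 1000), collapse = ""))
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  n <- length(ccg)
  set.seed(6)
  ## perfectly coupled: delta_ext = delta_int exactly
  mutLev <- runif(n, 0.1, 0.7)
  wt <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+", 0.8,
                    total = 1000L)
  mutC <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+",
                      rep(mutLev, 2), total = 1000L)
  expect_equal(internalExternalCorrelation(wt, mutC, ccg)$rho, 1)
  ## independent deltas
  mutI <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+",
                      runif(2L * n, 0.1, 0.7), total = 1000L)
  expect_lt(abs(internalExternalCorrelation(wt, mutI, ccg)$rho), 0.1)
})

test_that("selection filters and the minimum-site rule are enforced", {
  genome <- c(chr1 = "ACCGTTTACCGTTT")
  anno <- annotateCytosines(genome)
  ccg <- findCCGSites(anno)
  wt <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+", 0.4)
  mut <- makeProfile("chr1", c(ccg$externalPos, ccg$internalPos), "+", 0.2)
  ## nothing passes the reference filter at 0.5
  expect_error(internalExternalCorrelation(wt, mut, ccg), "fewer than 3")
})
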