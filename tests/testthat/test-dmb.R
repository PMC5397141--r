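test_that("score test matches hand-computed values", {
  st <- scoreTest(c(5, 20, 8), c(10, 20, 10), c(5, 0, 2), c(10, 20, 10))
  expect_equal(st$z[1], 0)
  expect_equal(st$p[1], 1)
  expect_equal(st$z[2], 6.3245553, tolerance = 1e-7)
  expect_equal(st$p[2], 2.5396285e-10, tolerance = 1e-6)
  expect_equal(st$z[3], 2.6832816, tolerance = 1e-7)
  ## p equals the chi-square(1) tail of z^2 = 7.2
  expect_equal(st$p[3], pchisq(7.2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  ## degenerate pooled proportions
  expect_equal(scoreTest(0, 10, 0, 10)$z, 0)
  expect_equal(scoreTest(10, 10, 10, 10)$p, 1)
  expect_error(scoreTest(1, 0, 1, 5), "positive")
  expect_error(scoreTest(6, 5, 1, 5), "0 <= m <= n")
})

test_that("z squared equals the Pearson chi-square statistic", {
  set.seed(71)
  n1 <- sample(1:60, 2000, replace = TRUE)
  n2 <- sample(1:60, 2000, replace = TRUE)
  m1 <- rbinom(2000, n1, runif(2000))
  m2 <- rbinom(2000, n2, runif(2000))
  st <- scoreTest(m1, n1, m2, n2)
  for (i in seq_len(2000)) {
    tab <- matrix(c(m1[i], n1[i] - m1[i], m2[i], n2[i] - m2[i]), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    x2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(st$z[i]^2, unname(x2), tolerance = 1e-10)
    expect_equal(st$p[i], pchisq(unname(x2), 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("score-test decisions mostly agree with Fisher's exact test", {
  ## depths from 5 (the coverage filter's minimum) up to 30 reads; half the
  ## tables drawn under the null, half with independent proportions
  set.seed(72)
  N <- 2000
  n1 <- sample(5:30, N, replace = TRUE)
  n2 <- sample(5:30, N, replace = TRUE)
  p1 <- runif(N)
  p2 <- ifelse(runif(N) < 0.5, p1, runif(N))
  m1 <- rbinom(N, n1, p1)
  m2 <- rbinom(N, n2, p2)
  st <- scoreTest(m1, n1, m2, n2)
  agree <- vapply(seq_len(N), function(i) {
    fp <- fisher.test(matrix(c(m1[i], n1[i] - m1[i], m2[i], n2[i] - m2[i]),
                             nrow = 2))$p.value
    (st$p[i] < 0.01) == (fp < 0.01)
  }, logical(1))
  expect_gt(mean(agree), 0.95)
})

test_that("identical profiles yield zero DMBs", {
  sim <- simulateMethylomes(smallSimConfig(seed = 73, coverage = 15),
                            mutants = character(0))
  p <- sim$profiles$wt
  for (ctx in c("CG", "CHG"))
    expect_length(callDMBs(p, p, sim$annotations, ctx), 0L)
})

test_that("a planted 90-vs-0 CHG bin is called as a loss", {
  ## ten CHG cytosines inside one 100-bp bin
  genome <- c(chr1 = paste0(paste(rep("CAGTTTTTT", 10), collapse = ""),
                            paste(rep("A", 110), collapse = "")))
  anno <- annotateCytosines(genome)
  chg <- anno[anno$context == "CHG"]
  a <- profileFromAnnotations(anno,
                              ifelse(as.character(anno$context) == "CHG",
                                     0.9, 0), total = 10L)
  b <- profileFromAnnotations(anno, rep(0, length(anno)), total = 10L)
  dmbs <- callDMBs(a, b, anno, "CHG")
  expect_length(dmbs, 1L)
  expect_equal(GenomicRanges::start(dmbs), 1L)
  expect_equal(GenomicRanges::width(dmbs), 100L)
  expect_equal(dmbs$direction, "loss")
  expect_gte(dmbs$diff, 0.2)
  expect_lt(dmbs$p, 0.01)
})

test_that("raising the effect-size threshold never adds DMBs", {
  sim <- simulateMethylomes(smallSimConfig(seed = 74, coverage = 20),
                            mutants = "cmt2-3")
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.6), function(d)
    length(callDMBs(sim$profiles$wt, sim$profiles$`cmt2-3`,
                    sim$annotations, "CHG", diffMin = d)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[3], 0)   # the cmt2/3 contrast does produce CHG DMBs
})

test_that("bin pooling uses pooled reads and respects the filters", {
  genome <- c(chr1 = paste(rep("CAGTTTTTT", 10), collapse = ""))
  anno <- annotateCytosines(genome)
  a <- profileFromAnnotations(anno, rep(0.6, length(anno)), total = 10L)
  b <- profileFromAnnotations(anno, rep(0.1, length(anno)), total = 10L)
  bins <- binScoreTests(a, b, anno, "CHG")
  expect_equal(bins$totalA[1], 10L * sum(as.character(anno$context) == "CHG" &
                                           GenomicRanges::start(anno) <= 100))
  expect_equal(bins$levelA[1], 0.6)
  expect_equal(bins$diff[1], 0.5)
  ## insufficient mean depth blocks the call
  expect_length(callDMBs(a, b, anno, "CHG", minMeanReads = 11), 0L)
  ## insufficient cytosine count blocks the call
  expect_length(callDMBs(a, b, anno, "CHG", minCytosines = 100), 0L)
})

test_that("interval overlap statistics distinguish containment", {
  gr <- function(s, e) GenomicRanges::GRanges("chr1",
                                              IRanges::IRanges(s, e - 1L))
  a <- c(gr(100, 200), gr(100, 200), gr(100, 200))
  b <- c(gr(50, 300), gr(150, 250), gr(500, 600))
  ov <- overlapDMBs(a[1], b[1])
  expect_equal(unname(ov$counts["contained"]), 1L)
  ov2 <- overlapDMBs(a[2], b[2])
  expect_equal(unname(ov2$counts["partial"]), 1L)
  ov3 <- overlapDMBs(a[3], b[3])
  expect_equal(unname(ov3$counts["disjoint"]), 1L)
})
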