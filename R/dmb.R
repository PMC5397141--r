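#' Two-proportion score test on methylation counts
#'
#' Tests equality of the methylation proportions of two samples given
#' methylated and total read counts. Under the pooled proportion
#' `phat = (m1 + m2) / (n1 + n2)` the statistic is
#' `z = (m1/n1 - m2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with a
#' two-sided p-value from the standard normal; `z^2` is identical to the
#' (uncorrected) Pearson chi-square statistic of the 2x2 table, and the
#' decision behaves like a Fisher's exact test at moderate depth. When the
#' pooled proportion is 0 or 1 the statistic is defined as 0 (p = 1).
#' All arguments are vectorized.
#'
#' @param m1,n1 Methylated and total reads in sample 1 (`0 <= m1 <= n1`,
#'   `n1 > 0`).
#' @param m2,n2 Same for sample 2.
#' @return A data.frame with columns `z` and `p`.
#' @examples
#' scoreTest(20, 20, 0, 20)   # z = 6.3246, p = 2.5e-10
#' @export
scoreTest <- function(m1, n1, m2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("total read counts must be positive")
  if (any(m1 < 0) || any(m2 < 0) || any(m1 > n1) || any(m2 > n2))
    stop("methylated reads must satisfy 0 <= m <= n")
  phat <- (m1 + m2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(phat <= 0 | phat >= 1, 0, (m1 / n1 - m2 / n2) / se)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

## Tiling bins anchored at position 1, last partial tile kept. Returns a
## GRanges over the seqlengths of `annotations` (1-based, closed ranges of
## width `binWidth`, i.e. [start, start + width) half-open in spirit).
.tilingBins <- function(annotations, binWidth) {
  sl <- seqlengths(annotations)
  if (anyNA(sl))
    sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ch) {
      max(end(annotations[seqnames(annotations) == ch]), 0L)
    }, numeric(1))
  starts <- lapply(sl, function(L) seq.int(1L, L, by = binWidth))
  gr <- GRanges(rep(names(sl), lengths(starts)),
                IRanges(unlist(starts, use.names = FALSE), width = binWidth))
  seqlevels(gr) <- names(sl)
  suppressWarnings(seqlengths(gr) <- sl)
  GenomicRanges::trim(gr)
}

#' Per-bin pooled methylation counts and score tests
#'
#' Tiles the genome into fixed-width bins anchored at position 1 (the last
#' partial bin is kept), pools methylated and total reads over all
#' cytosines of the requested context inside each bin (pooled-read
#' proportions, not means of per-cytosine levels, define bin methylation),
#' and applies [scoreTest()] to every bin covered in both samples.
#'
#' @param profileA,profileB [MethylationProfile-class] objects on the same
#'   genome.
#' @param annotations Output of [annotateCytosines()].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param binWidth Bin width in bp (default 100).
#' @param subcontexts Optional character vector restricting to trinucleotide
#'   subcontexts (e.g. `c("CAG", "CTG")` or `"CCG"`); `NULL` uses the whole
#'   context.
#' @return A `GRanges` of all bins with at least one context cytosine,
#'   with metadata columns `context`, `nCytosines`, `methA`, `totalA`,
#'   `methB`, `totalB`, `meanReadsA`, `meanReadsB`, `levelA`, `levelB`,
#'   `diff` (levelA - levelB), `z`, `p` (`NA` for bins lacking reads in
#'   either sample).
#' @seealso [callDMBs()]
#' @export
binScoreTests <- function(profileA, profileB, annotations, context,
                          binWidth = 100, subcontexts = NULL) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  sel <- as.character(annotations$context) == context
  if (!is.null(subcontexts))
    sel <- sel & annotations$subcontext %in% subcontexts
  cyt <- annotations[sel]
  keys <- .annoKey(cyt)
  ia <- match(keys, .annoKey(profileA@sites))
  ib <- match(keys, .annoKey(profileB@sites))
  keep <- !is.na(ia) & !is.na(ib)
  cyt <- cyt[keep]; ia <- ia[keep]; ib <- ib[keep]
  bins <- .tilingBins(annotations, binWidth)
  hit <- findOverlaps(cyt, bins)
  dt <- data.table::data.table(
    bin = subjectHits(hit),
    methA = profileA@meth[ia][queryHits(hit)],
    totalA = profileA@total[ia][queryHits(hit)],
    methB = profileB@meth[ib][queryHits(hit)],
    totalB = profileB@total[ib][queryHits(hit)])
  agg <- dt[, list(nCytosines = .N, methA = sum(methA), totalA = sum(totalA),
                   methB = sum(methB), totalB = sum(totalB)), by = "bin"]
  data.table::setorder(agg, bin)
  out <- bins[agg$bin]
  testable <- agg$totalA > 0L & agg$totalB > 0L
  z <- p <- rep(NA_real_, nrow(agg))
  if (any(testable)) {
    st <- scoreTest(agg$methA[testable], agg$totalA[testable],
                    agg$methB[testable], agg$totalB[testable])
    z[testable] <- st$z
    p[testable] <- st$p
  }
  mcols(out) <- DataFrame(
    context = context,
    nCytosines = agg$nCytosines,
    methA = agg$methA, totalA = agg$totalA,
    methB = agg$methB, totalB = agg$totalB,
    meanReadsA = agg$totalA / agg$nCytosines,
    meanReadsB = agg$totalB / agg$nCytosines,
    levelA = ifelse(agg$totalA > 0L, agg$methA / agg$totalA, NA_real_),
    levelB = ifelse(agg$totalB > 0L, agg$methB / agg$totalB, NA_real_),
    diff = ifelse(testable, agg$methA / agg$totalA - agg$methB / agg$totalB,
                  NA_real_),
    z = z, p = p)
  out
}

#' Call differentially methylated bins (DMBs)
#'
#' Runs [binScoreTests()] on fixed 100-bp tiling bins and retains bins
#' passing, conjunctively, the score-test p-value cutoff, a context-specific
#' methylation-difference filter (40% for CpG, 20% for CpHpG, 10% for
#' CpHpH), a minimum cytosine count, and a minimum mean read depth per
#' cytosine in each sample. Raw p-values are used by default; set
#' `adjust = TRUE` for Benjamini-Hochberg adjusted p-values instead.
#'
#' @inheritParams binScoreTests
#' @param pMax Strict p-value cutoff (default 0.01).
#' @param diffMin Minimum absolute methylation difference; default depends
#'   on `context`: CG 0.40, CHG 0.20, CHH 0.10.
#' @param minCytosines Minimum number of context cytosines in the bin
#'   (default 4, inclusive).
#' @param minMeanReads Minimum mean reads per cytosine, enforced in both
#'   samples (default 4, inclusive).
#' @param adjust Apply Benjamini-Hochberg correction before the p cutoff
#'   (default `FALSE`).
#' @param merge Merge adjacent same-direction DMBs into unions (default
#'   `FALSE`); merged ranges keep only the `direction` column.
#' @return A `GRanges` of DMBs (metadata as in [binScoreTests()] plus
#'   `direction`: `"loss"` where sample B lost methylation relative to A,
#'   `"gain"` where it gained), in genome order.
#' @export
callDMBs <- function(profileA, profileB, annotations, context,
                     binWidth = 100, pMax = 0.01,
                     diffMin = c(CG = 0.40, CHG = 0.20, CHH = 0.10)[[context]],
                     minCytosines = 4, minMeanReads = 4,
                     subcontexts = NULL, adjust = FALSE, merge = FALSE) {
  bins <- binScoreTests(profileA, profileB, annotations, context,
                        binWidth = binWidth, subcontexts = subcontexts)
  p <- bins$p
  if (adjust)
    p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & p < pMax &
    abs(bins$diff) >= diffMin &
    bins$nCytosines >= minCytosines &
    bins$meanReadsA >= minMeanReads & bins$meanReadsB >= minMeanReads
  out <- bins[keep]
  mcols(out)$direction <- ifelse(out$diff > 0, "loss", "gain")
  if (merge && length(out)) {
    merged <- lapply(c("loss", "gain"), function(d) {
      m <- reduce(out[out$direction == d], min.gapwidth = 1L)
      if (length(m)) mcols(m)$direction <- d
      m
    })
    out <- do.call(c, merged)
    out <- out[order(as.factor(seqnames(out)), start(out))]
  }
  out
}

#' Containment and overlap statistics between two interval sets
#'
#' For each interval of `setA`, reports whether it is fully contained in an
#' interval of `setB`, partially overlaps one, or is disjoint from all of
#' them. Used e.g. to ask whether regions gaining CpHpG methylation in a
#' later mutant generation include the DMBs of an earlier one.
#'
#' @param setA,setB `GRanges` interval sets.
#' @return A list with `perInterval` (factor over `setA`) and `counts`
#'   (named integer vector: contained, partial, disjoint).
#' @export
overlapDMBs <- function(setA, setB) {
  contained <- countOverlaps(setA, setB, type = "within",
                             ignore.strand = TRUE) > 0L
  touching <- countOverlaps(setA, setB, ignore.strand = TRUE) > 0L
  cls <- ifelse(contained, "contained",
                ifelse(touching, "partial", "disjoint"))
  cls <- factor(cls, levels = c("contained", "partial", "disjoint"))
  list(perInterval = cls, counts = c(table(cls)))
}
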