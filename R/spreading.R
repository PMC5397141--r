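#' Select doubly methylated CpCpG seed sites
#'
#' Seed sites are CpCpG occurrences whose external cytosine was essentially
#' unmethylated in the wild type (level strictly below `wtMax`) but gained
#' methylation in the mutant (strictly above `mutMin`), i.e. sites that
#' became ^mCp^mCpG. Each seed is additionally flagged as isolated when no
#' other seed lies within `isolationRadius` bp on the same chromosome
#' (regardless of strand); isolation is symmetric between seed pairs.
#'
#' @param wt,mutant [MethylationProfile-class] objects.
#' @param ccgSites Output of [findCCGSites()].
#' @param wtMax Strict WT upper bound on the external level (default 0.15).
#' @param mutMin Strict mutant lower bound on the external level
#'   (default 0.25).
#' @param isolationRadius Isolation distance in bp (default 500).
#' @return A width-1 `GRanges` at the external cytosine positions with
#'   strand and metadata `wtLevel`, `mutantLevel`, `isolated`.
#' @export
selectSeedSites <- function(wt, mutant, ccgSites, wtMax = 0.15,
                            mutMin = 0.25, isolationRadius = 500) {
  extKey <- .ccgExternalKey(ccgSites)
  wtLev <- .levelsAtKeys(wt, extKey)
  muLev <- .levelsAtKeys(mutant, extKey)
  keep <- !is.na(wtLev) & !is.na(muLev) & wtLev < wtMax & muLev > mutMin
  seeds <- GRanges(seqnames(ccgSites)[keep],
                   IRanges(ccgSites$externalPos[keep], width = 1L),
                   strand = strand(ccgSites)[keep],
                   seqinfo = seqinfo(ccgSites))
  near <- countOverlaps(seeds, seeds, maxgap = isolationRadius,
                        ignore.strand = TRUE) - 1L
  mcols(seeds) <- DataFrame(wtLevel = wtLev[keep], mutantLevel = muLev[keep],
                            isolated = near == 0L)
  seeds[order(as.factor(seqnames(seeds)), start(seeds))]
}

#' Distance-resolved methylation-change profile around seed sites
#'
#' For every seed, every covered cytosine of the requested context set
#' within `window` bp contributes its methylation change (mutant minus WT)
#' to the distance bin of its signed seed-relative position; a cytosine in
#' the window of k seeds contributes k times, once per seed. Distances are
#' oriented 5'->3' on the seed's strand (positive = downstream of the
#' seed's external cytosine), so upstream/downstream asymmetry is
#' observable; `fold = TRUE` pools the two sides on \eqn{|d|} (the variant
#' used for decay fitting). Cytosines that are themselves seed external
#' positions are excluded to avoid self-counting.
#'
#' @param seeds Output of [selectSeedSites()].
#' @param wt,mutant [MethylationProfile-class] objects.
#' @param annotations Output of [annotateCytosines()].
#' @param subcontexts Trinucleotide subcontexts to profile (default
#'   `c("CAG", "CTG")`, the CpHpG sites not part of a CpCpG); ignored when
#'   `contexts` is given.
#' @param contexts Optional context classes (e.g. `"CG"` for the
#'   no-change control profile).
#' @param window Half-window in bp (default 2000).
#' @param binWidth Distance bin width in bp (default 50).
#' @param isolatedOnly Use only isolated seeds (default `FALSE`).
#' @param fold Fold the profile on `|distance|` (default `FALSE`).
#' @return A data.frame with `binStart`, `binMid`, `meanDelta` and `n`
#'   (contributions per bin); empty bins are absent.
#' @export
distanceProfile <- function(seeds, wt, mutant, annotations,
                            subcontexts = c("CAG", "CTG"), contexts = NULL,
                            window = 2000, binWidth = 50,
                            isolatedOnly = FALSE, fold = FALSE) {
  if (isolatedOnly)
    seeds <- seeds[seeds$isolated]
  if (length(seeds) == 0L)
    stop("no seed sites")
  if (!is.null(contexts)) {
    sel <- as.character(annotations$context) %in% contexts
  } else {
    if (length(subcontexts) == 0L)
      stop("empty context set")
    sel <- annotations$subcontext %in% subcontexts
  }
  if (!any(sel))
    stop("empty context set")
  cyt <- annotations[sel]
  ## drop cytosines that are themselves seed externals (any seed, any strand)
  seedKey <- paste0(as.character(seqnames(seeds)), ":", start(seeds))
  cyt <- cyt[!paste0(as.character(seqnames(cyt)), ":", start(cyt)) %in%
               seedKey]
  keys <- .annoKey(cyt)
  delta <- .levelsAtKeys(mutant, keys) - .levelsAtKeys(wt, keys)
  covered <- !is.na(delta)
  cyt <- cyt[covered]; delta <- delta[covered]
  win <- GenomicRanges::trim(suppressWarnings(
    resize(seeds, 2L * window + 1L, fix = "center")))
  hit <- findOverlaps(win, cyt, ignore.strand = TRUE)
  if (length(hit) == 0L)
    return(data.frame(binStart = numeric(0), binMid = numeric(0),
                      meanDelta = numeric(0), n = integer(0)))
  sPos <- start(seeds)[queryHits(hit)]
  sStr <- as.character(strand(seeds))[queryHits(hit)]
  d <- (start(cyt)[subjectHits(hit)] - sPos) * ifelse(sStr == "+", 1L, -1L)
  ## half-open window [-window, window) so every distance bin is full width
  keepD <- d >= -window & d < window
  d <- d[keepD]
  hit <- hit[keepD]
  if (fold)
    d <- abs(d)
  dt <- data.table::data.table(
    bin = floor(d / binWidth),
    delta = delta[subjectHits(hit)])
  agg <- dt[, list(meanDelta = mean(delta), n = .N), by = "bin"]
  data.table::setorder(agg, bin)
  data.frame(binStart = agg$bin * binWidth,
             binMid = agg$bin * binWidth + binWidth / 2,
             meanDelta = agg$meanDelta, n = agg$n)
}

#' Fit an exponential decay to a distance profile
#'
#' Fits `a * exp(-|d| / lambda)` to the binned mean methylation changes by
#' weighted least squares (weights = contributions per bin), pooling the
#' two sides of a signed profile on `|d|`. The decay length `lambda` is the
#' distance over which the planted or observed spreading signal falls to
#' 1/e of its amplitude. A profile with no signal returns amplitude 0, and
#' a non-decreasing profile is reported with a poor-fit warning rather
#' than an error.
#'
#' @param profile Output of [distanceProfile()] (signed or folded).
#' @param minBins Minimum number of non-empty bins required (default 5).
#' @return A list with `amplitude`, `lambda` (bp), `rss` (weighted residual
#'   sum of squares) and `poorFit` (logical).
#' @export
fitDecay <- function(profile, minBins = 5) {
  dt <- data.table::data.table(d = abs(profile$binMid),
                               delta = profile$meanDelta, n = profile$n)
  agg <- dt[, list(delta = stats::weighted.mean(delta, n), n = sum(n)),
            by = "d"]
  data.table::setorder(agg, d)
  if (nrow(agg) < minBins)
    stop("fewer than ", minBins, " non-empty distance bins")
  if (all(abs(agg$delta) < 1e-8))
    return(list(amplitude = 0, lambda = NA_real_, rss = 0, poorFit = FALSE))
  ## log-linear start values from the positive bins
  pos <- agg$delta > 0
  if (sum(pos) >= 2L) {
    dd <- as.data.frame(agg[pos, ])
    lmfit <- stats::lm(log(delta) ~ d, data = dd, weights = dd$n)
    a0 <- exp(stats::coef(lmfit)[[1L]])
    l0 <- -1 / min(stats::coef(lmfit)[[2L]], -1e-6)
  } else {
    a0 <- max(agg$delta)
    l0 <- max(agg$d) / 2
  }
  a0 <- min(max(a0, 1e-3), 1)
  l0 <- min(max(l0, 1), 1e5)
  fit <- tryCatch(
    minpack.lm::nlsLM(delta ~ a * exp(-d / lambda), data = agg,
                      start = list(a = a0, lambda = l0), weights = agg$n,
                      lower = c(a = -1, lambda = 1),
                      upper = c(a = 1, lambda = 1e6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("decay fit did not converge; returning start values")
    return(list(amplitude = a0, lambda = l0, rss = NA_real_, poorFit = TRUE))
  }
  co <- stats::coef(fit)
  rss <- sum(agg$n * stats::residuals(fit)^2)
  ## flag fits where the profile does not actually decrease with distance
  half <- agg$d <= stats::median(agg$d)
  poorFit <- stats::weighted.mean(agg$delta[half], agg$n[half]) <=
    stats::weighted.mean(agg$delta[!half], agg$n[!half])
  if (poorFit)
    warning("profile is not decreasing with distance; decay fit unreliable")
  list(amplitude = unname(co["a"]), lambda = unname(co["lambda"]),
       rss = rss, poorFit = poorFit)
}
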