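#' Per-tile context methylation means and CpCpG status
#'
#' Partitions the genome into fixed-width tiles (default 500 bp, anchored at
#' position 1) and computes, per tile, the mean of per-cytosine methylation
#' levels over covered cytosines for each context (this is deliberately a
#' mean of levels, not a pooled-read proportion as in [binScoreTests()];
#' both conventions are in routine use and are documented side by side),
#' together with the number of CpCpG sites whose external cytosine falls in
#' the tile and how many of those have a methylated internal cytosine
#' (level at least `internalMin` in this profile; internals without
#' coverage are not counted as methylated).
#'
#' @param profile A [MethylationProfile-class] (coverage-filtered upstream
#'   if desired).
#' @param annotations Output of [annotateCytosines()].
#' @param ccgSites Output of [findCCGSites()].
#' @param width Tile width in bp (default 500).
#' @param internalMin Binarization threshold for a methylated internal
#'   cytosine (default 0.5).
#' @return A `GRanges` of tiles with metadata columns `meanCG`, `meanCHG`,
#'   `meanCHH` (`NA` where the tile has no covered cytosine of that
#'   context), `nCCG`, `nCCGInternalMeth` and `fracInternalMeth` (`NA`
#'   where `nCCG` is 0).
#' @export
tileMethylation <- function(profile, annotations, ccgSites, width = 500,
                            internalMin = 0.5) {
  tiles <- .tilingBins(annotations, width)
  lev <- methLevel(profile)
  aidx <- match(.annoKey(profile@sites), .annoKey(annotations))
  if (anyNA(aidx))
    stop("profile contains sites lacking a cytosine annotation")
  ctx <- as.character(annotations$context)[aidx]
  covered <- !is.na(lev) & ctx %in% c("CG", "CHG", "CHH")
  hit <- findOverlaps(profile@sites[covered], tiles)
  dt <- data.table::data.table(tile = subjectHits(hit),
                               context = ctx[covered][queryHits(hit)],
                               level = lev[covered][queryHits(hit)])
  agg <- dt[, list(mean = mean(level)), by = c("tile", "context")]
  m <- matrix(NA_real_, nrow = length(tiles), ncol = 3L,
              dimnames = list(NULL, c("CG", "CHG", "CHH")))
  m[cbind(agg$tile, match(agg$context, colnames(m)))] <- agg$mean

  extGR <- GRanges(seqnames(ccgSites), IRanges(ccgSites$externalPos,
                                               width = 1L))
  tileOfExt <- findOverlaps(extGR, tiles, select = "first")
  intLev <- .levelsAtKeys(profile, .ccgInternalKey(ccgSites))
  intMeth <- !is.na(intLev) & intLev >= internalMin
  nCCG <- tabulate(tileOfExt, nbins = length(tiles))
  nMeth <- tabulate(tileOfExt[intMeth], nbins = length(tiles))
  mcols(tiles) <- DataFrame(meanCG = unname(m[, "CG"]),
                            meanCHG = unname(m[, "CHG"]),
                            meanCHH = unname(m[, "CHH"]),
                            nCCG = nCCG, nCCGInternalMeth = nMeth,
                            fracInternalMeth =
                              ifelse(nCCG > 0L, nMeth / nCCG, NA_real_))
  tiles
}

TILE_CLASSES <- c("gbM_IBM1_target", "gbM_IBM1_independent", "TE", "other")

#' Classify tiles into TE, IBM1-target and IBM1-independent gbM classes
#'
#' Applies the rule cascade used to separate gene-body-methylated regions by
#' their response to loss of the H3K9me2 demethylase IBM1: a tile is a
#' transposable element (TE) when its WT CpHpG mean is at least `teChgMin`;
#' otherwise it is gene-body methylated (gbM) when WT CpG is at least
#' `gbmCgMin` and WT CpHpG and CpHpH are each strictly below `gbmNoncgMax`.
#' gbM tiles gaining at least `targetGainMin` CpHpG methylation in the ibm1
#' mutant are IBM1 targets; those gaining strictly less than
#' `independentGainMax` are IBM1-independent; gbM tiles in between, tiles
#' failing all rules, and tiles with undefined means are `other`. Classes
#' are mutually exclusive with precedence TE, then gbM subtypes.
#'
#' @param wtTiles,ibm1Tiles Outputs of [tileMethylation()] on identical
#'   tilings for wild type and the ibm1 mutant.
#' @param gbmCgMin Minimum WT CpG mean for gbM (default 0.10, inclusive).
#' @param gbmNoncgMax Strict upper bound on WT CpHpG and CpHpH for gbM
#'   (default 0.05).
#' @param targetGainMin Minimum ibm1 CpHpG gain for an IBM1 target
#'   (default 0.50, inclusive).
#' @param independentGainMax Strict upper bound on gain for
#'   IBM1-independence (default 0.05).
#' @param teChgMin Minimum WT CpHpG mean for a TE (default 0.50, inclusive).
#' @return A factor over tiles with levels `gbM_IBM1_target`,
#'   `gbM_IBM1_independent`, `TE`, `other`.
#' @export
classifyTiles <- function(wtTiles, ibm1Tiles, gbmCgMin = 0.10,
                          gbmNoncgMax = 0.05, targetGainMin = 0.50,
                          independentGainMax = 0.05, teChgMin = 0.50) {
  if (length(wtTiles) != length(ibm1Tiles) ||
      any(start(wtTiles) != start(ibm1Tiles)) ||
      any(as.character(seqnames(wtTiles)) != as.character(seqnames(ibm1Tiles))))
    stop("'wtTiles' and 'ibm1Tiles' must be on the same tiling")
  cls <- rep("other", length(wtTiles))
  isTE <- !is.na(wtTiles$meanCHG) & wtTiles$meanCHG >= teChgMin
  isGbm <- !isTE &
    !is.na(wtTiles$meanCG) & !is.na(wtTiles$meanCHG) &
    !is.na(wtTiles$meanCHH) &
    wtTiles$meanCG >= gbmCgMin & wtTiles$meanCHG < gbmNoncgMax &
    wtTiles$meanCHH < gbmNoncgMax
  gain <- ibm1Tiles$meanCHG - wtTiles$meanCHG
  cls[isTE] <- "TE"
  cls[isGbm & !is.na(gain) & gain >= targetGainMin] <- "gbM_IBM1_target"
  cls[isGbm & !is.na(gain) & gain < independentGainMax] <-
    "gbM_IBM1_independent"
  factor(cls, levels = TILE_CLASSES)
}

#' CpCpG site counts and internal methylation status per tile
#'
#' Convenience accessor over [tileMethylation()] output: the number of
#' CpCpG sites per tile, the number with a methylated internal cytosine in
#' the reference sample, and their fraction. Because the ibm1 mutation does
#' not affect CpG methylation, the internal status may be read from an ibm1
#' sample in place of the wild type.
#'
#' @param tiles Output of [tileMethylation()].
#' @return A data.frame with `nCCG`, `nCCGInternalMeth`, `fracInternalMeth`.
#' @export
ccgStatusPerTile <- function(tiles) {
  data.frame(nCCG = tiles$nCCG, nCCGInternalMeth = tiles$nCCGInternalMeth,
             fracInternalMeth = tiles$fracInternalMeth)
}

#' Predict IBM1 targets from the presence of internally methylated CpCpGs
#'
#' Within gbM tiles, predicts "IBM1 target" wherever the tile contains at
#' least `minSites` CpCpG site with a methylated internal cytosine
#' (a Cp^mCpG), and evaluates the prediction against an observed
#' classification (from [classifyTiles()] or a planted truth), restricted
#' to tiles labelled target or independent.
#'
#' @param tiles Output of [tileMethylation()] for the sample whose internal
#'   cytosine status is trusted (WT, or ibm1 since CpG methylation is
#'   unaffected by ibm1).
#' @param classes Factor from [classifyTiles()] (or a logical/character
#'   vector marking true targets) parallel to `tiles`.
#' @param minSites Minimum number of internally methylated CpCpG sites that
#'   predicts a target (default 1).
#' @param within Optional logical vector restricting which tiles enter the
#'   evaluation (e.g. the gene-body tiles when `classes` is a planted
#'   truth). When `classes` is a [classifyTiles()] factor the evaluation
#'   is always restricted to tiles labelled target or independent.
#' @return A list with `predicted` (logical per tile), `confusion` (2x2
#'   table over evaluated tiles), `precision`, `recall`, `nEvaluated`.
#' @export
predictIBM1Targets <- function(tiles, classes, minSites = 1, within = NULL) {
  predicted <- tiles$nCCGInternalMeth >= minSites
  if (is.factor(classes) || is.character(classes)) {
    evaluated <- classes %in% c("gbM_IBM1_target", "gbM_IBM1_independent")
    truth <- classes == "gbM_IBM1_target"
  } else {
    evaluated <- rep(TRUE, length(classes))
    truth <- as.logical(classes)
  }
  if (!is.null(within))
    evaluated <- evaluated & within
  pe <- predicted[evaluated]; te <- truth[evaluated]
  confusion <- table(predicted = pe, target = te)
  tp <- sum(pe & te)
  list(predicted = predicted, confusion = confusion,
       precision = if (sum(pe)) tp / sum(pe) else NA_real_,
       recall = if (sum(te)) tp / sum(te) else NA_real_,
       nEvaluated = sum(evaluated))
}

#' Compare homologous bins between two ecotypes
#'
#' Consumes a homologous-bin table (e.g. derived from a whole-genome
#' alignment of the Col-0 and Ler-0 assemblies; the alignment itself is
#' performed by external tools) and classifies each bin pair by its ibm1
#' CpHpG methylation in the two ecotypes: `A_only` (at least `gainMin` in
#' ecotype A and strictly below `nogainMax` in B), `B_only` (the mirror
#' image), `both` (at least `gainMin` in both) or `neither`. Pairs must
#' satisfy the homology invariants: alignment length within
#' `alnRange` and at least one CpCpG site; offending rows are rejected
#' with a reason. Per class, the distribution of internally methylated
#' CpCpG counts in each ecotype is summarised.
#'
#' @param pairs A data.frame with columns `chgA`, `chgB` (ibm1 CpHpG tile
#'   methylation per ecotype), `nCCG` (CpCpG sites in the bin),
#'   `nInternalMethA`, `nInternalMethB` (internally methylated CpCpG counts
#'   per ecotype) and `alnLen` (alignment length in bp). Extra columns
#'   (bin ids, intervals) are carried through.
#' @param gainMin Inclusive methylation threshold for a gain (default
#'   0.50).
#' @param nogainMax Strict threshold for "no gain" (default 0.05).
#' @param alnRange Allowed alignment-length range (default `c(400, 600)`,
#'   inclusive).
#' @param labels Names of the two ecotypes, used in class labels
#'   (default `c("Col", "Ler")`).
#' @return A list with `pairs` (accepted rows plus a `class` factor),
#'   `rejected` (rows failing the invariants, with `reason`), and
#'   `summary` (per class: n, median and mean `nInternalMeth` per ecotype).
#' @export
compareEcotypes <- function(pairs, gainMin = 0.50, nogainMax = 0.05,
                            alnRange = c(400, 600),
                            labels = c("Col", "Ler")) {
  need <- c("chgA", "chgB", "nCCG", "nInternalMethA", "nInternalMethB",
            "alnLen")
  if (!all(need %in% names(pairs)))
    stop("'pairs' must have columns: ", paste(need, collapse = ", "))
  reason <- rep(NA_character_, nrow(pairs))
  reason[pairs$alnLen < alnRange[1] | pairs$alnLen > alnRange[2]] <-
    "alignment length outside range"
  reason[pairs$nCCG < 1] <- "no CpCpG site"
  rejected <- cbind(pairs[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  ok <- pairs[is.na(reason), , drop = FALSE]
  clsLevels <- c(paste0(labels[1], "_only"), paste0(labels[2], "_only"),
                 "both", "neither")
  cls <- rep("neither", nrow(ok))
  cls[ok$chgA >= gainMin & ok$chgB >= gainMin] <- "both"
  cls[ok$chgA >= gainMin & ok$chgB < nogainMax] <- clsLevels[1]
  cls[ok$chgB >= gainMin & ok$chgA < nogainMax] <- clsLevels[2]
  ok$class <- factor(cls, levels = clsLevels)
  summ <- do.call(rbind, lapply(clsLevels, function(cl) {
    x <- ok[ok$class == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(x),
               medianInternalMethA = stats::median(x$nInternalMethA),
               medianInternalMethB = stats::median(x$nInternalMethB),
               meanInternalMethA = mean(x$nInternalMethA),
               meanInternalMethB = mean(x$nInternalMethB))
  }))
  list(pairs = ok, rejected = rejected, summary = summ)
}
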