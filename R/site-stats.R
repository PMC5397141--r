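#' Per-context relative methylation change between mutant and wild type
#'
#' For every filtered site, computes the relative change in methylation
#' level, `(mutant - WT) / WT`, and summarises its distribution per
#' sequence-context class. The classes separate the CpHpG subcontexts so the
#' behaviour of CpCpG external cytosines can be contrasted with CpApG and
#' CpTpG: `CG` (all CpG-context cytosines), `CAG`, `CTG`, `CCG` (external
#' cytosines of CpCpG occurrences) and `CHH`. Relative change is undefined
#' at WT level 0; such sites are excluded (they never pass the WT
#' methylation filter anyway). A complete loss gives -1, no change gives 0.
#'
#' @param wt,mutant [MethylationProfile-class] objects.
#' @param siteSet `GRanges` of sites to evaluate (typically the output of
#'   [filterWTMethylated()]).
#' @param annotations Output of [annotateCytosines()].
#' @return A list with `perSite` (data.frame: key, class, wtLevel,
#'   mutantLevel, relChange) and `summary` (per-class n, quartiles, mean).
#' @export
contextContrast <- function(wt, mutant, siteSet, annotations) {
  keys <- .annoKey(siteSet)
  aidx <- match(keys, .annoKey(annotations))
  if (anyNA(aidx))
    stop("some sites in 'siteSet' lack a cytosine annotation")
  ctx <- as.character(annotations$context)[aidx]
  sub <- annotations$subcontext[aidx]
  cls <- rep(NA_character_, length(keys))
  cls[ctx == "CG"] <- "CG"
  cls[ctx == "CHH"] <- "CHH"
  cls[sub == "CAG"] <- "CAG"
  cls[sub == "CTG"] <- "CTG"
  cls[sub == "CCG"] <- "CCG"
  wtLev <- .levelsAtKeys(wt, keys)
  muLev <- .levelsAtKeys(mutant, keys)
  ok <- !is.na(cls) & !is.na(wtLev) & !is.na(muLev) & wtLev > 0
  perSite <- data.frame(key = keys[ok],
                        class = factor(cls[ok], levels = CONTRAST_CLASSES),
                        wtLevel = wtLev[ok], mutantLevel = muLev[ok],
                        relChange = (muLev[ok] - wtLev[ok]) / wtLev[ok],
                        stringsAsFactors = FALSE)
  empty <- setdiff(CONTRAST_CLASSES, as.character(perSite$class))
  if (length(empty))
    warning("no usable sites in context class(es): ",
            paste(empty, collapse = ", "))
  summ <- do.call(rbind, lapply(CONTRAST_CLASSES, function(cl) {
    x <- perSite$relChange[perSite$class == cl]
    if (length(x) == 0L)
      return(data.frame(class = cl, n = 0L, q25 = NA_real_, median = NA_real_,
                        q75 = NA_real_, mean = NA_real_))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = cl, n = length(x), q25 = q[1], median = q[2],
               q75 = q[3], mean = mean(x))
  }))
  list(perSite = perSite, summary = summ)
}

CONTRAST_CLASSES <- c("CG", "CAG", "CTG", "CCG", "CHH")

#' Classify CpCpG external cytosines as CMT2/3- or RdDM-dependent
#'
#' Compares the external-cytosine methylation level of each CpCpG site in a
#' cmt2/3 double mutant with the wild type. Sites losing at least 99% of
#' their WT methylation (`mutant <= cdcMaxFrac * WT`) are CMT2/3-dependent
#' (CDC); sites retaining more than 20% (`mutant > rdcMinFrac * WT`) are
#' RdDM-dependent (RDC); the remainder are `ambiguous` rather than forced
#' into a class. Sites with WT level 0 or missing coverage in either sample
#' are unclassifiable and excluded.
#'
#' @param wt,cmt23 [MethylationProfile-class] objects for wild type and the
#'   cmt2/3 double mutant.
#' @param ccgSites Output of [findCCGSites()].
#' @param cdcMaxFrac,rdcMinFrac Fractions of the WT level bounding the CDC
#'   and RDC calls (defaults 0.01 and 0.20).
#' @return A data.frame with one row per classified site: external key,
#'   WT and mutant external levels, and `label` in
#'   `c("CDC", "RDC", "ambiguous")`.
#' @export
classifyCCGDependency <- function(wt, cmt23, ccgSites,
                                  cdcMaxFrac = 0.01, rdcMinFrac = 0.20) {
  keys <- .ccgExternalKey(ccgSites)
  wtLev <- .levelsAtKeys(wt, keys)
  muLev <- .levelsAtKeys(cmt23, keys)
  ok <- !is.na(wtLev) & !is.na(muLev) & wtLev > 0
  wtLev <- wtLev[ok]; muLev <- muLev[ok]
  label <- rep("ambiguous", sum(ok))
  label[muLev <= cdcMaxFrac * wtLev] <- "CDC"
  label[muLev > rdcMinFrac * wtLev] <- "RDC"
  data.frame(key = keys[ok], wtLevel = wtLev, mutantLevel = muLev,
             label = factor(label, levels = c("CDC", "RDC", "ambiguous")),
             stringsAsFactors = FALSE)
}

#' Joint internal/external methylation pattern of CpCpG sites
#'
#' Binarizes the external and internal cytosine levels of every CpCpG site
#' at `threshold` (at/above = `M`, below = `U`) and reports the joint
#' pattern, first letter external, second internal: `UU` (both
#' unmethylated), `UM` (internal only), `MM` (both), and the "forbidden"
#' `MU` (external only), which in real plant methylomes is almost completely
#' absent. Sites with either cytosine uncovered are skipped and counted.
#'
#' @param profile A [MethylationProfile-class].
#' @param ccgSites Output of [findCCGSites()].
#' @param threshold Binarization threshold (default 0.5).
#' @return A list with `perSite` (data.frame: externalKey, externalLevel,
#'   internalLevel, pattern), `freq` (named frequencies over classified
#'   sites, summing to 1), `counts` and `nSkipped`.
#' @export
ccgPattern <- function(profile, ccgSites, threshold = 0.5) {
  extLev <- .levelsAtKeys(profile, .ccgExternalKey(ccgSites))
  intLev <- .levelsAtKeys(profile, .ccgInternalKey(ccgSites))
  ok <- !is.na(extLev) & !is.na(intLev)
  pat <- paste0(ifelse(extLev[ok] >= threshold, "M", "U"),
                ifelse(intLev[ok] >= threshold, "M", "U"))
  pat <- factor(pat, levels = c("UU", "UM", "MM", "MU"))
  counts <- table(pat)
  freq <- if (sum(counts) > 0) as.numeric(counts) / sum(counts) else
    rep(NA_real_, 4L)
  names(freq) <- names(counts)
  list(perSite = data.frame(externalKey = .ccgExternalKey(ccgSites)[ok],
                            externalLevel = extLev[ok],
                            internalLevel = intLev[ok],
                            pattern = pat, stringsAsFactors = FALSE),
       freq = freq, counts = counts, nSkipped = sum(!ok))
}

#' Correlation of internal and external methylation changes at CpCpG sites
#'
#' Selects CpCpG sites with both cytosines methylated at `refMin` or more in
#' the reference sample (and, optionally, below `selectionMax` in a second
#' selection sample, as used when asking whether methylation regained after
#' complementation returns to the same sites), then computes per-site
#' changes of the internal and external cytosines between `sample` and
#' `reference` and their Spearman rank correlation (average ranks on ties).
#' By default changes are relative to the reference level
#' (`(sample - reference) / reference`), so a value of -1 is a complete
#' loss; `type = "absolute"` uses plain level differences instead.
#'
#' @param reference,sample [MethylationProfile-class] objects; changes are
#'   `sample` minus `reference`.
#' @param ccgSites Output of [findCCGSites()].
#' @param refMin Minimum reference-level of both cytosines for a site to be
#'   selected (default 0.5).
#' @param selection Optional third [MethylationProfile-class]; when given,
#'   selected sites must additionally have both cytosines strictly below
#'   `selectionMax` in it.
#' @param selectionMax Upper bound used with `selection` (default 0.40).
#' @param type `"relative"` (default) or `"absolute"` changes.
#' @return A list with `pairs` (data.frame: externalKey, deltaInternal,
#'   deltaExternal), `rho` (Spearman coefficient) and `n`.
#' @export
internalExternalCorrelation <- function(reference, sample, ccgSites,
                                        refMin = 0.50, selection = NULL,
                                        selectionMax = 0.40,
                                        type = c("relative", "absolute")) {
  type <- match.arg(type)
  extKey <- .ccgExternalKey(ccgSites)
  intKey <- .ccgInternalKey(ccgSites)
  refExt <- .levelsAtKeys(reference, extKey)
  refInt <- .levelsAtKeys(reference, intKey)
  smpExt <- .levelsAtKeys(sample, extKey)
  smpInt <- .levelsAtKeys(sample, intKey)
  keep <- !is.na(refExt) & !is.na(refInt) & !is.na(smpExt) & !is.na(smpInt) &
    refExt >= refMin & refInt >= refMin
  if (!is.null(selection)) {
    selExt <- .levelsAtKeys(selection, extKey)
    selInt <- .levelsAtKeys(selection, intKey)
    keep <- keep & !is.na(selExt) & !is.na(selInt) &
      selExt < selectionMax & selInt < selectionMax
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 CpCpG sites pass the selection; ",
         "correlation undefined")
  dExt <- smpExt[keep] - refExt[keep]
  dInt <- smpInt[keep] - refInt[keep]
  if (type == "relative") {
    dExt <- dExt / refExt[keep]
    dInt <- dInt / refInt[keep]
  }
  rho <- stats::cor(dInt, dExt, method = "spearman")
  list(pairs = data.frame(externalKey = extKey[keep], deltaInternal = dInt,
                          deltaExternal = dExt, stringsAsFactors = FALSE),
       rho = rho, n = sum(keep))
}
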