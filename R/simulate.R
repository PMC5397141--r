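#' SimulationConfig: parameters of the synthetic methylome generator
#'
#' Bundles every parameter of the synthetic genome and methylome generator.
#' The generator emulates the structure the analysis consumes: a genome
#' partitioned into gene bodies (CpG-only methylation), transposable
#' elements (methylation in all contexts) and unmethylated background;
#' CpCpG external cytosines methylated only when their internal cytosine is
#' methylated, and then only with probability `qExt`; a fraction `rdmFrac`
#' of methylated externals maintained by the RdDM pathway; and rule-derived
#' mutant methylomes (met1-3, met1-1, cmt2/3, ddcc, ibm1). All randomness
#' is driven by `seed`, so a config fully determines the output.
#'
#' @slot seed Integer master seed.
#' @slot chromLengths Named numeric; chromosome lengths in bp (multiples of
#'   `tileWidth`).
#' @slot tileWidth Tile width used for planted-target bookkeeping (bp).
#' @slot geneLength,teLength Lengths of gene-body and TE intervals (bp,
#'   multiples of `tileWidth`).
#' @slot geneFraction,teFraction Fractions of the genome covered by gene
#'   bodies and TEs.
#' @slot baseProbs Named probabilities of A, C, G, T (plant-like ~36% GC by
#'   default).
#' @slot pTargetGene Probability that a gene body is a planted IBM1 target,
#'   i.e. carries methylated CpCpG internal cytosines.
#' @slot pInternalMeth Within a target gene, probability that each CpCpG
#'   internal dyad is methylated (default 1: in real IBM1-target bins
#'   nearly all internal cytosines are methylated); at least one per target
#'   gene is always planted, and the value 0 plants exactly one, at the
#'   CpCpG nearest the gene midpoint (the configuration used for spreading
#'   analyses).
#' @slot geneCGShape,teCGShape,teCHGShape,teCHHShape Beta shape pairs for
#'   methylated-site levels per compartment and context.
#' @slot epsilon Noise floor for unmethylated cytosines (real bisulfite
#'   data never sit at exactly 0).
#' @slot qExt Probability that an internally methylated CpCpG in a TE is
#'   also externally methylated (default 0.4).
#' @slot rdmFrac Fraction of methylated CpCpG externals flagged
#'   RdDM-dependent.
#' @slot rdcRetentionRange Uniform range of the WT fraction retained by
#'   RdDM-dependent externals in cmt2/3.
#' @slot cdcRetentionMax Upper bound of the WT fraction retained by
#'   CMT2/3-dependent externals in cmt2/3 (residual far below 1% of WT, per
#'   the CDC definition, which is relative to the WT level).
#' @slot ibm1Amplitude,ibm1Lambda Amplitude and decay length (bp) of the
#'   exponential CpHpG spreading kernel planted in the ibm1 mutant.
#' @slot met1RetentionShape Beta shape pair of the per-dyad CpG retention
#'   factor in the met1-1 hypomorph (default mean 0.25).
#' @slot met1Rho Planted Spearman correlation between internal and external
#'   retention at CpCpG sites in met1-1 (Gaussian copula on retention
#'   ranks).
#' @slot coverage Mean sequencing depth per cytosine.
#' @slot dispersion Negative-binomial size for coverage; `NA` (default)
#'   uses Poisson coverage.
#' @seealso [simulationConfig()], [simulateMethylomes()]
#' @export
setClass("SimulationConfig",
         representation(seed = "integer", chromLengths = "numeric",
                        tileWidth = "numeric", geneLength = "numeric",
                        teLength = "numeric", geneFraction = "numeric",
                        teFraction = "numeric", baseProbs = "numeric",
                        pTargetGene = "numeric", pInternalMeth = "numeric",
                        geneCGShape = "numeric", teCGShape = "numeric",
                        teCHGShape = "numeric", teCHHShape = "numeric",
                        epsilon = "numeric", qExt = "numeric",
                        rdmFrac = "numeric",
                        rdcRetentionRange = "numeric",
                        cdcRetentionMax = "numeric",
                        ibm1Amplitude = "numeric", ibm1Lambda = "numeric",
                        met1RetentionShape = "numeric", met1Rho = "numeric",
                        coverage = "numeric", dispersion = "numeric"))

setValidity("SimulationConfig", function(object) {
  probs <- c(object@geneFraction, object@teFraction, object@pTargetGene,
             object@pInternalMeth, object@qExt, object@rdmFrac,
             object@met1Rho)
  if (any(probs < 0 | probs > 1))
    return("all probabilities must lie in [0, 1]")
  if (object@geneFraction + object@teFraction > 1)
    return("geneFraction + teFraction must not exceed 1")
  if (object@ibm1Lambda <= 0)
    return("ibm1Lambda must be positive")
  if (object@ibm1Amplitude < 0 || object@ibm1Amplitude > 1)
    return("ibm1Amplitude must lie in [0, 1]")
  if (object@epsilon < 0 || object@epsilon >= 0.5)
    return("epsilon must lie in [0, 0.5)")
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    return("chromLengths must be a named vector of positive lengths")
  if (any(object@chromLengths %% object@tileWidth != 0))
    return("chromosome lengths must be multiples of tileWidth")
  if (object@geneLength %% object@tileWidth != 0 ||
      object@teLength %% object@tileWidth != 0)
    return("geneLength and teLength must be multiples of tileWidth")
  if (abs(sum(object@baseProbs) - 1) > 1e-8 ||
      !identical(sort(names(object@baseProbs)), c("A", "C", "G", "T")))
    return("baseProbs must be named A, C, G, T and sum to 1")
  if (object@coverage < 0)
    return("coverage must be non-negative")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|",
      sum(object@chromLengths), "bp in", length(object@chromLengths),
      "chromosome(s) |", "coverage", object@coverage, "x\n")
  cat("  gene fraction", object@geneFraction, "(length",
      object@geneLength, "bp), TE fraction", object@teFraction,
      "| qExt", object@qExt, "| rdmFrac", object@rdmFrac, "\n")
  cat("  ibm1 kernel a =", object@ibm1Amplitude, ", lambda =",
      object@ibm1Lambda, "bp | met1-1 rho =", object@met1Rho, "\n")
})

#' Construct a SimulationConfig
#'
#' All arguments have defaults describing a desk-scale two-chromosome
#' genome (200 kb) with plant-like compartments; see
#' [SimulationConfig-class] for the meaning of each parameter.
#'
#' @param seed Master seed (integer).
#' @param chromLengths,tileWidth,geneLength,teLength,geneFraction,teFraction
#'   Genome layout parameters.
#' @param baseProbs Base composition.
#' @param pTargetGene,pInternalMeth,geneCGShape,teCGShape,teCHGShape,teCHHShape
#'   Methylation-state parameters.
#' @param epsilon,qExt,rdmFrac,rdcRetentionRange,cdcRetentionMax Noise floor
#'   and CpCpG external-methylation parameters.
#' @param ibm1Amplitude,ibm1Lambda,met1RetentionShape,met1Rho Mutant-rule
#'   parameters.
#' @param coverage,dispersion Read-sampling parameters.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(seed = 7, chromLengths = c(chr1 = 50000))
#' @export
simulationConfig <- function(seed = 1,
                             chromLengths = c(chr1 = 120000, chr2 = 80000),
                             tileWidth = 500, geneLength = 1000,
                             teLength = 1000, geneFraction = 0.30,
                             teFraction = 0.25,
                             baseProbs = c(A = 0.32, C = 0.18, G = 0.18,
                                           T = 0.32),
                             pTargetGene = 1 / 3, pInternalMeth = 1,
                             geneCGShape = c(60, 10),
                             teCGShape = c(60, 10),
                             teCHGShape = c(42, 18),
                             teCHHShape = c(6, 14),
                             epsilon = 0.01, qExt = 0.4, rdmFrac = 0.2,
                             rdcRetentionRange = c(0.4, 0.8),
                             cdcRetentionMax = 0.001,
                             ibm1Amplitude = 0.75, ibm1Lambda = 300,
                             met1RetentionShape = c(0.4, 1.2),
                             met1Rho = 0.87,
                             coverage = 30, dispersion = NA_real_) {
  new("SimulationConfig", seed = as.integer(seed),
      chromLengths = chromLengths, tileWidth = tileWidth,
      geneLength = geneLength, teLength = teLength,
      geneFraction = geneFraction, teFraction = teFraction,
      baseProbs = baseProbs[c("A", "C", "G", "T")],
      pTargetGene = pTargetGene, pInternalMeth = pInternalMeth,
      geneCGShape = geneCGShape, teCGShape = teCGShape,
      teCHGShape = teCHGShape, teCHHShape = teCHHShape, epsilon = epsilon,
      qExt = qExt, rdmFrac = rdmFrac,
      rdcRetentionRange = rdcRetentionRange,
      cdcRetentionMax = cdcRetentionMax,
      ibm1Amplitude = ibm1Amplitude, ibm1Lambda = ibm1Lambda,
      met1RetentionShape = met1RetentionShape, met1Rho = met1Rho,
      coverage = coverage, dispersion = dispersion)
}

## Does this interval sequence contain at least one usable CCG occurrence
## (either strand, internal cytosine annotatable)?
.hasCCG <- function(chars) {
  s <- paste(chars, collapse = "")
  grepl("CCG[ACGT]", s) || grepl("[ACGT]CGG", s)
}

#' Generate a synthetic genome with gene and TE intervals
#'
#' Draws i.i.d. bases at the configured composition and lays out
#' non-overlapping gene-body and TE intervals aligned to the tile grid.
#' Every gene and TE interval is guaranteed to contain at least one usable
#' CpCpG occurrence (the interval sequence is re-drawn until it does, with
#' a bounded number of retries). Deterministic given `config@seed`.
#'
#' @param config A [SimulationConfig-class].
#' @param maxRetries Resampling bound per interval (default 100).
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `genes` and
#'   `tes` (`GRanges`).
#' @export
generateGenome <- function(config, maxRetries = 100) {
  set.seed(config@seed)
  bases <- c("A", "C", "G", "T")
  probs <- config@baseProbs
  chroms <- names(config@chromLengths)
  seqs <- list(); genes <- list(); tes <- list()
  for (ch in chroms) {
    L <- config@chromLengths[[ch]]
    v <- sample(bases, L, replace = TRUE, prob = probs)
    nGene <- floor(L * config@geneFraction / config@geneLength)
    nTE <- floor(L * config@teFraction / config@teLength)
    lens <- c(rep(config@geneLength, nGene), rep(config@teLength, nTE))
    types <- c(rep("gene", nGene), rep("te", nTE))
    nBg <- (L - sum(lens)) / config@tileWidth
    lens <- c(lens, rep(config@tileWidth, nBg))
    types <- c(types, rep("bg", nBg))
    o <- sample(length(lens))
    lens <- lens[o]; types <- types[o]
    starts <- cumsum(c(1, lens))[seq_along(lens)]
    for (i in which(types != "bg")) {
      idx <- starts[i]:(starts[i] + lens[i] - 1L)
      tries <- 0L
      while (!.hasCCG(v[idx])) {
        tries <- tries + 1L
        if (tries > maxRetries)
          stop("could not place a CpCpG site in a ", types[i],
               " interval after ", maxRetries, " retries")
        v[idx] <- sample(bases, lens[i], replace = TRUE, prob = probs)
      }
    }
    seqs[[ch]] <- paste(v, collapse = "")
    genes[[ch]] <- starts[types == "gene"]
    tes[[ch]] <- starts[types == "te"]
  }
  si <- Seqinfo(chroms, seqlengths = config@chromLengths)
  toGR <- function(startList, width) {
    GRanges(rep(chroms, lengths(startList)),
            IRanges(unlist(startList, use.names = FALSE), width = width),
            seqinfo = si)
  }
  list(genome = DNAStringSet(unlist(seqs)),
       genes = toGR(genes, config@geneLength),
       tes = toGR(tes, config@teLength))
}

## Dyad key of CpG-context annotations: both strands of a symmetric CpG
## dyad share one key (the forward-strand C position); NA for non-CpG.
.dyadKeys <- function(annotations) {
  ctx <- as.character(annotations$context)
  pos <- start(annotations)
  str <- as.character(strand(annotations))
  key <- rep(NA_character_, length(annotations))
  isCG <- ctx == "CG"
  key[isCG] <- paste0(as.character(seqnames(annotations))[isCG], ":",
                      ifelse(str[isCG] == "+", pos[isCG], pos[isCG] - 1L))
  key
}

#' Generate the wild-type true methylation state
#'
#' Assigns a true methylation level to every annotated cytosine following
#' the compartment rules: gene bodies carry CpG-only methylation (CpCpG
#' internal dyads methylated only in planted IBM1-target genes), TEs carry
#' methylation in all contexts, background sits at the noise floor.
#' Symmetric CpG dyads share one level on both strands (CpG maintenance is
#' strand-symmetric); CHG strand symmetry is not enforced. TE CpCpG
#' external cytosines are methylated only when the internal cytosine is
#' methylated, and then with probability `qExt` — the forbidden
#' external-only (MU) pattern never occurs in the truth. A fraction
#' `rdmFrac` of methylated externals is flagged RdDM-dependent.
#'
#' @param genomeParts Output of [generateGenome()].
#' @param annotations Output of [annotateCytosines()] on that genome.
#' @param ccgSites Output of [findCCGSites()].
#' @param config The [SimulationConfig-class].
#' @param stateSeed Seed for the state draw (default `config@seed + 1`);
#'   distinct seeds over the same genome give independent states, the
#'   construction used for the two-ecotype mode.
#' @param targetFlags Optional logical vector over `genomeParts$genes`
#'   forcing which genes are planted IBM1 targets (default: Bernoulli
#'   `pTargetGene` per gene).
#' @return A list (the "WT state") with `levels` (true level per
#'   annotation), `targetGenes`, `targetTiles`, `rdmFlag` (per CpCpG site:
#'   `TRUE` RdDM-dependent, `FALSE` CMT2/3-dependent, `NA` external
#'   unmethylated), the index vectors linking CpCpG sites to annotations,
#'   and the inputs (`annotations`, `ccgSites`, `genes`, `tes`, `config`).
#' @export
generateWTState <- function(genomeParts, annotations, ccgSites, config,
                            stateSeed = config@seed + 1L,
                            targetFlags = NULL) {
  set.seed(stateSeed)
  eps <- config@epsilon
  n <- length(annotations)
  ctx <- as.character(annotations$context)
  sub <- annotations$subcontext
  genes <- genomeParts$genes; tes <- genomeParts$tes
  inGene <- IRanges::overlapsAny(annotations, genes,
                                       ignore.strand = TRUE)
  inTE <- IRanges::overlapsAny(annotations, tes, ignore.strand = TRUE)
  key <- .annoKey(annotations)
  extIdx <- match(.ccgExternalKey(ccgSites), key)
  intIdx <- match(.ccgInternalKey(ccgSites), key)
  levels <- rep(eps, n)

  ## --- CpG dyads ---------------------------------------------------------
  dyad <- .dyadKeys(annotations)
  isCG <- !is.na(dyad)
  udyad <- unique(dyad[isCG])
  dyadOf <- match(dyad, udyad)
  ## compartment and CCG-internal status per dyad (either member qualifies)
  dyadGene <- dyadTE <- rep(FALSE, length(udyad))
  dyadGene[dyadOf[isCG & inGene]] <- TRUE
  dyadTE[dyadOf[isCG & inTE]] <- TRUE
  dyadCCGInt <- rep(FALSE, length(udyad))
  dyadCCGInt[dyadOf[intIdx]] <- TRUE
  ## planted target genes
  if (is.null(targetFlags))
    targetFlags <- stats::runif(length(genes)) < config@pTargetGene
  stopifnot(length(targetFlags) == length(genes))
  ## gene of each CCG-internal dyad (via the internal annotation position)
  dyadLevel <- rep(eps, length(udyad))
  geneDraw <- stats::rbeta(length(udyad), config@geneCGShape[1],
                           config@geneCGShape[2])
  teDraw <- stats::rbeta(length(udyad), config@teCGShape[1],
                         config@teCGShape[2])
  dyadLevel[dyadTE] <- teDraw[dyadTE]
  plainGene <- dyadGene & !dyadTE & !dyadCCGInt
  dyadLevel[plainGene] <- geneDraw[plainGene]
  ## CCG-internal dyads inside genes: methylated only in target genes
  geneOfInt <- findOverlaps(annotations[intIdx], genes, select = "first",
                            ignore.strand = TRUE)
  intDyad <- dyadOf[intIdx]
  for (g in which(targetFlags)) {
    dy <- unique(intDyad[!is.na(geneOfInt) & geneOfInt == g])
    if (length(dy) == 0L)
      next
    meth <- stats::runif(length(dy)) < config@pInternalMeth
    if (!any(meth)) {
      ## force the dyad nearest the gene midpoint
      mid <- (start(genes)[g] + end(genes)[g]) / 2
      sitePos <- vapply(dy, function(d) {
        i <- intIdx[match(d, intDyad)]
        start(annotations)[i]
      }, numeric(1))
      meth[which.min(abs(sitePos - mid))] <- TRUE
    }
    dyadLevel[dy[meth]] <- geneDraw[dy[meth]]
  }
  levels[isCG] <- dyadLevel[dyadOf[isCG]]

  ## --- TE non-CpG contexts ----------------------------------------------
  teCHG <- inTE & sub %in% c("CAG", "CTG")
  levels[teCHG] <- stats::rbeta(sum(teCHG), config@teCHGShape[1],
                                config@teCHGShape[2])
  teCHH <- inTE & ctx == "CHH"
  levels[teCHH] <- stats::rbeta(sum(teCHH), config@teCHHShape[1],
                                config@teCHHShape[2])
  ## TE CpCpG externals: conditional on a methylated internal, prob qExt
  extTE <- inTE[extIdx]
  intMeth <- levels[intIdx] >= 0.5
  extOn <- extTE & intMeth & stats::runif(length(extIdx)) < config@qExt
  levels[extIdx[extOn]] <- stats::rbeta(sum(extOn), config@teCHGShape[1],
                                        config@teCHGShape[2])
  ## RdDM dependence flags over methylated externals
  rdmFlag <- rep(NA, length(extIdx))
  rdmFlag[extOn] <- stats::runif(sum(extOn)) < config@rdmFrac

  targetGenes <- genes[targetFlags]
  tiles <- .tilingBins(annotations, config@tileWidth)
  targetTiles <- tiles[IRanges::overlapsAny(tiles, targetGenes,
                                                  ignore.strand = TRUE)]
  list(levels = levels, annotations = annotations, ccgSites = ccgSites,
       genes = genes, tes = tes, targetFlags = targetFlags,
       targetGenes = targetGenes, targetTiles = targetTiles,
       rdmFlag = rdmFlag, extIdx = extIdx, intIdx = intIdx,
       dyadOf = dyadOf, config = config)
}

.normalizeMutantId <- function(mutantId) {
  id <- gsub("[/_ ]", "-", tolower(mutantId))
  known <- c("met1-3", "met1-1", "cmt2-3", "ddcc", "ibm1")
  if (!id %in% known)
    stop("unknown mutant id '", mutantId, "'; expected one of: ",
         paste(known, collapse = ", "))
  id
}

#' Derive a mutant true methylation state from the wild-type state
#'
#' Applies the genetic rules of the supported mutants to the WT truth:
#' \describe{
#'   \item{met1-3}{Null CpG methyltransferase: every CpG level and every
#'     CpCpG external level collapses to the noise floor; CpApG, CpTpG and
#'     CpHpH are unchanged.}
#'   \item{met1-1}{Hypomorph: each CpG dyad retains a Beta-distributed
#'     fraction of its WT level; the retention of each CpCpG external is
#'     coupled to its internal dyad's retention through a Gaussian copula
#'     with Spearman correlation `met1Rho`.}
#'   \item{cmt2-3}{CpApG and CpTpG collapse to the noise floor; CpCpG
#'     externals lose over 99% of their WT level unless flagged
#'     RdDM-dependent, in which case they retain a uniform fraction in
#'     `rdcRetentionRange`.}
#'   \item{ddcc}{All CpHpG and CpHpH levels collapse to the noise floor;
#'     CpG is unchanged.}
#'   \item{ibm1}{CpG and CpHpH unchanged. Within planted target genes,
#'     every CpHpG cytosine gains `ibm1Amplitude * exp(-d / ibm1Lambda)`
#'     where `d` is the distance to the nearest internally methylated
#'     CpCpG external in the same gene (capped at level 1); genes without
#'     an internally methylated CpCpG gain nothing.}
#' }
#'
#' @param wtState Output of [generateWTState()].
#' @param mutantId One of `"met1-3"`, `"met1-1"`, `"cmt2-3"` (aliases with
#'   `/` accepted), `"ddcc"`, `"ibm1"`.
#' @param mutantSeed Seed for the mutant's own randomness (default derived
#'   from the config seed and the mutant id).
#' @return A list with `levels`, `mutantId`, and for met1-1 the per-dyad
#'   `retention` and per-site external retention.
#' @export
deriveMutantState <- function(wtState, mutantId, mutantSeed = NULL) {
  id <- .normalizeMutantId(mutantId)
  config <- wtState$config
  if (is.null(mutantSeed))
    mutantSeed <- config@seed + 10L +
      match(id, c("met1-3", "met1-1", "cmt2-3", "ddcc", "ibm1"))
  set.seed(mutantSeed)
  eps <- config@epsilon
  anno <- wtState$annotations
  ctx <- as.character(anno$context)
  sub <- anno$subcontext
  lv <- wtState$levels
  extIdx <- wtState$extIdx; intIdx <- wtState$intIdx
  extra <- list()

  if (id == "met1-3") {
    lv[ctx == "CG"] <- eps
    lv[extIdx] <- eps
  } else if (id == "met1-1") {
    nd <- max(wtState$dyadOf, na.rm = TRUE)
    a <- config@met1RetentionShape[1]; b <- config@met1RetentionShape[2]
    rDyad <- stats::rbeta(nd, a, b)
    isCG <- !is.na(wtState$dyadOf)
    lv[isCG] <- lv[isCG] * rDyad[wtState$dyadOf[isCG]]
    ## Gaussian copula coupling external retention to the internal dyad's
    rhoP <- 2 * sin(pi * config@met1Rho / 6)
    rInt <- rDyad[wtState$dyadOf[intIdx]]
    z1 <- stats::qnorm(pmin(pmax(stats::pbeta(rInt, a, b), 1e-12),
                            1 - 1e-12))
    z2 <- rhoP * z1 + sqrt(1 - rhoP^2) * stats::rnorm(length(z1))
    rExt <- stats::qbeta(stats::pnorm(z2), a, b)
    lv[extIdx] <- wtState$levels[extIdx] * rExt
    extra <- list(retention = rDyad, externalRetention = rExt)
  } else if (id == "cmt2-3") {
    lv[sub %in% c("CAG", "CTG")] <- eps
    methExt <- !is.na(wtState$rdmFlag)
    rdc <- methExt & wtState$rdmFlag
    cdc <- methExt & !wtState$rdmFlag
    lv[extIdx[rdc]] <- wtState$levels[extIdx[rdc]] *
      stats::runif(sum(rdc), config@rdcRetentionRange[1],
                   config@rdcRetentionRange[2])
    lv[extIdx[cdc]] <- wtState$levels[extIdx[cdc]] *
      stats::runif(sum(cdc), 0, config@cdcRetentionMax)
  } else if (id == "ddcc") {
    lv[ctx %in% c("CHG", "CHH")] <- eps
  } else if (id == "ibm1") {
    a <- config@ibm1Amplitude; lambda <- config@ibm1Lambda
    intMeth <- wtState$levels[intIdx] >= 0.5
    seedPos <- wtState$ccgSites$externalPos
    annoPos <- start(anno)
    annoChrom <- as.character(seqnames(anno))
    extChrom <- as.character(seqnames(wtState$ccgSites))
    isCHG <- ctx == "CHG"
    ## CpCpG externals whose internal cytosine is unmethylated cannot gain:
    ## the external-only (MU) pattern is excluded by the coupling rule
    blockedExt <- extIdx[!intMeth]
    isCHG[blockedExt] <- FALSE
    genes <- wtState$genes
    geneOfExt <- findOverlaps(
      GRanges(extChrom, IRanges(seedPos, width = 1L)), genes,
      select = "first", ignore.strand = TRUE)
    chgGR <- anno[isCHG]
    geneOfCHG <- findOverlaps(chgGR, genes, select = "first",
                              ignore.strand = TRUE)
    chgIdx <- which(isCHG)
    for (g in seq_along(genes)) {
      seeds <- sort(unique(seedPos[!is.na(geneOfExt) & geneOfExt == g &
                                     intMeth]))
      if (length(seeds) == 0L)
        next
      ci <- chgIdx[!is.na(geneOfCHG) & geneOfCHG == g]
      if (length(ci) == 0L)
        next
      p <- annoPos[ci]
      j <- findInterval(p, seeds)
      dLeft <- ifelse(j >= 1L, p - seeds[pmax(j, 1L)], Inf)
      dRight <- ifelse(j < length(seeds), seeds[pmin(j + 1L,
                                                     length(seeds))] - p,
                       Inf)
      d <- pmin(dLeft, dRight)
      lv[ci] <- pmin(1, lv[ci] + a * exp(-d / lambda))
    }
  }
  c(list(levels = lv, mutantId = id), extra)
}

#' Sample read counts from a true methylation state
#'
#' Draws per-site total read counts (Poisson with the configured mean, or
#' negative binomial when `dispersion` is set; zero totals are allowed) and
#' methylated counts (binomial at the true level), yielding a
#' [MethylationProfile-class]. Deterministic given `sampleSeed`.
#'
#' @param levels Numeric true levels in `[0, 1]`, parallel to
#'   `annotations`.
#' @param annotations Output of [annotateCytosines()].
#' @param config The [SimulationConfig-class].
#' @param sampleSeed Seed for the read draw.
#' @param sampleId Sample identifier.
#' @param coverage Optional mean depth override (defaults to
#'   `config@coverage`).
#' @return A [MethylationProfile-class] over all annotated cytosines.
#' @export
sampleReads <- function(levels, annotations, config, sampleSeed,
                        sampleId = "sample", coverage = NULL) {
  stopifnot(length(levels) == length(annotations),
            all(levels >= 0 & levels <= 1))
  set.seed(sampleSeed)
  if (is.null(coverage))
    coverage <- config@coverage
  n <- length(levels)
  total <- if (is.na(config@dispersion))
    stats::rpois(n, coverage)
  else
    stats::rnbinom(n, mu = coverage, size = config@dispersion)
  meth <- stats::rbinom(n, total, levels)
  sites <- GRanges(seqnames(annotations),
                   IRanges(start(annotations), width = 1L),
                   strand = strand(annotations),
                   seqinfo = seqinfo(annotations))
  MethylationProfile(sites, meth = meth, total = total, sampleId = sampleId)
}

#' Simulate a full set of wild-type and mutant methylomes
#'
#' One-call orchestration of the generator: genome, annotations, CpCpG
#' sites, WT truth, rule-derived mutant truths and sampled read profiles,
#' everything deterministic given `config@seed`.
#'
#' @param config A [SimulationConfig-class].
#' @param mutants Character vector of mutant ids to derive (default all
#'   five supported).
#' @return A list with `genome`, `genes`, `tes`, `annotations`,
#'   `ccgSites`, `wtState`, `mutantStates` (named list), `profiles`
#'   (named list of [MethylationProfile-class], including `"wt"`) and
#'   `truth` (planted labels: `targetTiles`, `targetGenes`, `rdmFlag`,
#'   `lambda`, `rho`, `qExt`).
#' @examples
#' sim <- simulateMethylomes(
#'   simulationConfig(seed = 3, chromLengths = c(chr1 = 20000)),
#'   mutants = "ddcc")
#' sim$profiles$ddcc
#' @export
simulateMethylomes <- function(config,
                               mutants = c("met1-3", "met1-1", "cmt2-3",
                                           "ddcc", "ibm1")) {
  mutants <- vapply(mutants, .normalizeMutantId, character(1))
  parts <- generateGenome(config)
  anno <- annotateCytosines(parts$genome)
  ccg <- findCCGSites(anno)
  wtState <- generateWTState(parts, anno, ccg, config)
  mutantStates <- lapply(mutants, function(m) deriveMutantState(wtState, m))
  names(mutantStates) <- mutants
  profiles <- list(wt = sampleReads(wtState$levels, anno, config,
                                    sampleSeed = config@seed + 100L,
                                    sampleId = "wt"))
  for (i in seq_along(mutants))
    profiles[[mutants[i]]] <-
      sampleReads(mutantStates[[i]]$levels, anno, config,
                  sampleSeed = config@seed + 100L + i,
                  sampleId = mutants[i])
  list(genome = parts$genome, genes = parts$genes, tes = parts$tes,
       annotations = anno, ccgSites = ccg, wtState = wtState,
       mutantStates = mutantStates, profiles = profiles,
       truth = list(targetTiles = wtState$targetTiles,
                    targetGenes = wtState$targetGenes,
                    rdmFlag = wtState$rdmFlag,
                    lambda = config@ibm1Lambda, rho = config@met1Rho,
                    qExt = config@qExt, config = config))
}

#' Simulate two ecotypes sharing a genome with disjoint target genes
#'
#' Generates one genome and two independent wild-type states over it whose
#' planted IBM1-target gene sets are disjoint (each gene is a target of
#' ecotype A with probability `pTargetGene`, of B with the same
#' probability, or of neither), derives the ibm1 state per ecotype, samples
#' reads, and assembles the homologous-bin pair table consumed by
#' [compareEcotypes()] (identity mapping, alignment length = tile width,
#' gene-body tiles with at least one CpCpG site).
#'
#' @param config A [SimulationConfig-class].
#' @param labels Ecotype labels (default `c("Col", "Ler")`).
#' @return A list with per-ecotype states, profiles and tiles, and `pairs`
#'   ready for [compareEcotypes()].
#' @export
simulateEcotypes <- function(config, labels = c("Col", "Ler")) {
  parts <- generateGenome(config)
  anno <- annotateCytosines(parts$genome)
  ccg <- findCCGSites(anno)
  set.seed(config@seed + 20L)
  u <- stats::runif(length(parts$genes))
  p <- config@pTargetGene
  flagsA <- u < p
  flagsB <- u >= p & u < 2 * p
  stateA <- generateWTState(parts, anno, ccg, config,
                            stateSeed = config@seed + 21L,
                            targetFlags = flagsA)
  stateB <- generateWTState(parts, anno, ccg, config,
                            stateSeed = config@seed + 22L,
                            targetFlags = flagsB)
  ibm1A <- deriveMutantState(stateA, "ibm1",
                             mutantSeed = config@seed + 23L)
  ibm1B <- deriveMutantState(stateB, "ibm1",
                             mutantSeed = config@seed + 24L)
  profA <- sampleReads(ibm1A$levels, anno, config, config@seed + 25L,
                       paste0(labels[1], "_ibm1"))
  profB <- sampleReads(ibm1B$levels, anno, config, config@seed + 26L,
                       paste0(labels[2], "_ibm1"))
  tilesA <- tileMethylation(profA, anno, ccg, width = config@tileWidth)
  tilesB <- tileMethylation(profB, anno, ccg, width = config@tileWidth)
  geneTile <- IRanges::overlapsAny(tilesA, parts$genes,
                                         ignore.strand = TRUE)
  keep <- geneTile & tilesA$nCCG >= 1L
  pairs <- data.frame(
    chrom = as.character(seqnames(tilesA))[keep],
    start = start(tilesA)[keep], end = end(tilesA)[keep],
    chgA = tilesA$meanCHG[keep], chgB = tilesB$meanCHG[keep],
    nCCG = tilesA$nCCG[keep],
    nInternalMethA = tilesA$nCCGInternalMeth[keep],
    nInternalMethB = tilesB$nCCGInternalMeth[keep],
    alnLen = config@tileWidth, stringsAsFactors = FALSE)
  list(genome = parts$genome, genes = parts$genes, tes = parts$tes,
       annotations = anno, ccgSites = ccg,
       states = stats::setNames(list(stateA, stateB), labels),
       ibm1States = stats::setNames(list(ibm1A, ibm1B), labels),
       profiles = stats::setNames(list(profA, profB), labels),
       tiles = stats::setNames(list(tilesA, tilesB), labels),
       pairs = pairs)
}

#' Write planted truth labels to machine-readable files
#'
#' Emits the ground truth of a simulation for recovery tests: per-site true
#' levels per sample (TSV), CpCpG dependency flags (TSV; CDC/RDC partition
#' the methylated externals), planted target tiles (BED) and the scalar
#' parameters (JSON).
#'
#' @param sim Output of [simulateMethylomes()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
writeTruth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anno <- sim$annotations
  lvl <- data.table::data.table(
    chrom = as.character(seqnames(anno)), pos = start(anno),
    strand = as.character(strand(anno)), wt = sim$wtState$levels)
  for (m in names(sim$mutantStates))
    lvl[[m]] <- sim$mutantStates[[m]]$levels
  p1 <- file.path(dir, "true_levels.tsv")
  data.table::fwrite(lvl, p1, sep = "\t")
  flag <- sim$truth$rdmFlag
  ccg <- data.table::data.table(
    chrom = as.character(seqnames(sim$ccgSites)),
    externalPos = sim$ccgSites$externalPos,
    internalPos = sim$ccgSites$internalPos,
    strand = as.character(strand(sim$ccgSites)),
    externalMethylated = !is.na(flag),
    dependency = ifelse(is.na(flag), "none",
                        ifelse(flag, "RDC", "CDC")))
  p2 <- file.path(dir, "ccg_truth.tsv")
  data.table::fwrite(ccg, p2, sep = "\t")
  tt <- sim$truth$targetTiles
  p3 <- file.path(dir, "target_tiles.bed")
  data.table::fwrite(data.table::data.table(
    chrom = as.character(seqnames(tt)), start = start(tt) - 1L,
    end = end(tt)), p3, sep = "\t", col.names = FALSE)
  p4 <- file.path(dir, "params.json")
  jsonlite::write_json(list(lambda = sim$truth$lambda, rho = sim$truth$rho,
                            qExt = sim$truth$qExt,
                            seed = sim$truth$config@seed),
                       p4, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4))
}
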