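#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand mcols mcols<-
#'   findOverlaps reduce countOverlaps resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom data.table data.table fread fwrite setorder :=
NULL

.datatable.aware <- TRUE

CONTEXT_LEVELS <- c("CG", "CHG", "CHH", "unknown")

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Coerce genome input (DNAStringSet, named character vector, or FASTA path)
## to a named uppercase character vector, validating the alphabet.
.genomeAsCharacter <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
             is.null(names(genome)) && file.exists(genome)) {
    seqs <- as.character(readDNAStringSet(genome))
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("'genome' must be a DNAStringSet, a named character vector, ",
         "or a FASTA file path")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("genome sequences must have unique names")
  ## FASTA descriptions: keep the first word as the sequence name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
  }
  seqs
}

## Annotate one strand of one chromosome. `bases` is the forward-strand
## character vector; for the minus strand the two downstream bases lie at
## pos-1, pos-2 and are complemented so the trinucleotide reads 5'->3' on the
## cytosine's own strand.
.annotateStrand <- function(bases, strand) {
  L <- length(bases)
  if (strand == "+") {
    pos <- which(bases == "C")
    d1 <- if (length(pos)) bases[pmin(pos + 1L, L + 1L)] else character(0)
    d2 <- if (length(pos)) bases[pmin(pos + 2L, L + 2L)] else character(0)
    d1[pos + 1L > L] <- NA_character_
    d2[pos + 2L > L] <- NA_character_
  } else {
    pos <- which(bases == "G")
    d1 <- ifelse(pos - 1L >= 1L, .complement[bases[pmax(pos - 1L, 1L)]],
                 NA_character_)
    d2 <- ifelse(pos - 2L >= 1L, .complement[bases[pmax(pos - 2L, 1L)]],
                 NA_character_)
  }
  ok <- !is.na(d1) & !is.na(d2) & d1 != "N" & d2 != "N"
  subcontext <- rep("unknown", length(pos))
  subcontext[ok] <- paste0("C", d1[ok], d2[ok])
  context <- rep("unknown", length(pos))
  context[ok & d1 == "G"] <- "CG"
  context[ok & d1 != "G" & d2 == "G"] <- "CHG"
  context[ok & d1 != "G" & d2 != "G"] <- "CHH"
  list(pos = pos, strand = strand, context = context, subcontext = subcontext)
}

#' Annotate every cytosine of a genome by methylation context
#'
#' Scans both strands of a genome and emits one annotation per cytosine:
#' a 1-based forward-strand position, the strand carrying the cytosine, the
#' context class (`CG`, `CHG`, `CHH` or `unknown`) and the trinucleotide
#' subcontext read 5'->3' on the cytosine's own strand (e.g. `CAG`, `CCG`,
#' `CGT`). Cytosines with fewer than two determinate downstream bases on
#' their strand (sequence ends, or bases adjacent to `N`) are annotated
#' `unknown` and are excluded by all downstream analyses. Soft-masked
#' (lower-case) bases are treated as their upper-case equivalents.
#'
#' @param genome A [Biostrings::DNAStringSet], a named character vector of
#'   chromosome sequences, or the path to a (multi-record) FASTA file.
#'   Bases must be in `A`, `C`, `G`, `T`, `N` (case-insensitive).
#' @return A [GenomicRanges::GRanges] of width-1 ranges, one per cytosine on
#'   either strand, ordered by chromosome then position, with metadata
#'   columns `context` (factor) and `subcontext` (character). Sequence
#'   lengths are recorded in the `seqinfo`.
#' @examples
#' anno <- annotateCytosines(c(chr1 = "ACCGGT"))
#' anno
#' @seealso [findCCGSites()], [contextCensus()]
#' @export
annotateCytosines <- function(genome) {
  seqs <- .genomeAsCharacter(genome)
  parts <- lapply(names(seqs), function(chrom) {
    s <- seqs[[chrom]]
    if (nchar(s) == 0L)
      return(NULL)
    bases <- strsplit(s, "", fixed = TRUE)[[1L]]
    fwd <- .annotateStrand(bases, "+")
    rev <- .annotateStrand(bases, "-")
    n <- length(fwd$pos) + length(rev$pos)
    if (n == 0L)
      return(NULL)
    pos <- c(fwd$pos, rev$pos)
    o <- order(pos)
    data.frame(
      chrom = chrom,
      pos = pos[o],
      strand = c(rep("+", length(fwd$pos)), rep("-", length(rev$pos)))[o],
      context = c(fwd$context, rev$context)[o],
      subcontext = c(fwd$subcontext, rev$subcontext)[o],
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  si <- Seqinfo(seqnames = names(seqs), seqlengths = nchar(seqs))
  if (is.null(df))
    return(GRanges(seqinfo = si,
                   context = factor(character(0), levels = CONTEXT_LEVELS),
                   subcontext = character(0)))
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand,
                context = factor(df$context, levels = CONTEXT_LEVELS),
                subcontext = df$subcontext, seqinfo = si)
  gr
}

#' Discover and pair CpCpG sites
#'
#' A CpCpG site is an occurrence of the `CCG` motif on either strand: its
#' first cytosine (the "external" one) is in CHG context with subcontext
#' `CCG`, and its second cytosine (the "internal" one) is in CpG context.
#' Minus-strand sites arise from forward-strand `CGG` motifs. Sites whose
#' internal cytosine carries an `unknown` context (motifs truncated by a
#' sequence end or an adjacent `N`) are dropped, so no returned site overlaps
#' an unknown-context position.
#'
#' @param annotations Cytosine annotations from [annotateCytosines()] for the
#'   full genome (subsetting them beforehand breaks internal/external
#'   pairing and raises an error).
#' @return A [GenomicRanges::GRanges] of width-2 ranges covering the two
#'   cytosines, with strand, and metadata columns `externalPos` and
#'   `internalPos` (1-based forward-strand coordinates). On the plus strand
#'   `internalPos == externalPos + 1`; on the minus strand
#'   `internalPos == externalPos - 1`.
#' @examples
#' anno <- annotateCytosines(c(chr1 = "ACCGT"))
#' findCCGSites(anno)
#' @export
findCCGSites <- function(annotations) {
  key <- .annoKey(annotations)
  ext <- which(annotations$subcontext == "CCG")
  if (length(ext) == 0L) {
    gr <- GRanges(seqinfo = seqinfo(annotations))
    mcols(gr) <- DataFrame(externalPos = integer(0), internalPos = integer(0))
    return(gr)
  }
  extChrom <- as.character(seqnames(annotations))[ext]
  extStrand <- as.character(strand(annotations))[ext]
  extPos <- start(annotations)[ext]
  intPos <- ifelse(extStrand == "+", extPos + 1L, extPos - 1L)
  intIdx <- match(paste0(extChrom, ":", intPos, ":", extStrand), key)
  if (anyNA(intIdx))
    stop("internal partner cytosine missing from the annotations; ",
         "'annotations' must cover the full genome")
  intCtx <- as.character(annotations$context)[intIdx]
  if (any(!intCtx %in% c("CG", "unknown")))
    stop("internal partner of a CCG occurrence is not in CpG context; ",
         "malformed annotations")
  keep <- intCtx == "CG"
  extPos <- extPos[keep]; intPos <- intPos[keep]
  extChrom <- extChrom[keep]; extStrand <- extStrand[keep]
  gr <- GRanges(extChrom,
                IRanges(pmin(extPos, intPos), pmax(extPos, intPos)),
                strand = extStrand, seqinfo = seqinfo(annotations))
  mcols(gr) <- DataFrame(externalPos = as.integer(extPos),
                         internalPos = as.integer(intPos))
  gr[order(as.factor(seqnames(gr)), start(gr))]
}

#' Tabulate cytosine context and subcontext counts
#'
#' @param annotations Output of [annotateCytosines()].
#' @return A `data.frame` with columns `context`, `subcontext` and `n`;
#'   counts sum to `length(annotations)`.
#' @export
contextCensus <- function(annotations) {
  if (length(annotations) == 0L)
    return(data.frame(context = character(0), subcontext = character(0),
                      n = integer(0)))
  tab <- table(context = as.character(annotations$context),
               subcontext = annotations$subcontext)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("context", "subcontext", "n")
  df <- df[df$n > 0L, , drop = FALSE]
  df <- df[order(df$context, df$subcontext), , drop = FALSE]
  rownames(df) <- NULL
  df$n <- as.integer(df$n)
  df
}

## (chrom, pos, strand) keys used to join annotations, profiles and sites
.annoKey <- function(gr) {
  if (length(gr) == 0L)
    return(character(0))
  paste0(as.character(seqnames(gr)), ":", start(gr), ":",
         as.character(strand(gr)))
}

## Keys of external and internal cytosines of CCG sites
.ccgExternalKey <- function(ccgSites) {
  paste0(as.character(seqnames(ccgSites)), ":", ccgSites$externalPos, ":",
         as.character(strand(ccgSites)))
}

.ccgInternalKey <- function(ccgSites) {
  paste0(as.character(seqnames(ccgSites)), ":", ccgSites$internalPos, ":",
         as.character(strand(ccgSites)))
}

#' Export cytosine annotations as a tab-separated table
#'
#' @param annotations Output of [annotateCytosines()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeAnnotationTable <- function(annotations, path) {
  dt <- data.table::data.table(
    chrom = as.character(seqnames(annotations)),
    pos = start(annotations),
    strand = as.character(strand(annotations)),
    context = as.character(annotations$context),
    subcontext = annotations$subcontext)
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Export CpCpG sites as a BED-like table
#'
#' Writes half-open 0-based BED coordinates covering the two cytosines plus
#' the external/internal 1-based positions.
#'
#' @param ccgSites Output of [findCCGSites()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeCCGSites <- function(ccgSites, path) {
  dt <- data.table::data.table(
    chrom = as.character(seqnames(ccgSites)),
    start = start(ccgSites) - 1L,
    end = end(ccgSites),
    strand = as.character(strand(ccgSites)),
    externalPos = ccgSites$externalPos,
    internalPos = ccgSites$internalPos)
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
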