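#' Read a Bismark per-cytosine (CX) report
#'
#' Parses the tab-separated Bismark "cytosine report" format: chromosome,
#' 1-based position, strand, methylated read count, unmethylated read count,
#' context, trinucleotide. The context and trinucleotide columns are treated
#' as display-only; analyses take context labels from [annotateCytosines()]
#' so the genome sequence remains the single source of truth. Plain and
#' gzip-compressed files are both accepted.
#'
#' @param path Path to the CX report.
#' @param sampleId Sample identifier to attach; defaults to the file name.
#' @return A [MethylationProfile-class].
#' @seealso [writeCXReport()]
#' @export
readCXReport <- function(path, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.(txt|tsv|cov|CX_report)?(\\.gz)?$", "",
                    basename(path))
  if (file.exists(path) && file.size(path) == 0L)
    return(MethylationProfile(GRanges(), integer(0), integer(0), sampleId))
  cxCols <- list(colClasses = list(character = c(1L, 3L, 6L, 7L)),
                 col.names = c("chrom", "pos", "strand", "meth",
                               "unmeth", "context", "tri"))
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    txt <- readLines(con)
    if (length(txt) == 0L)
      return(MethylationProfile(GRanges(), integer(0), integer(0), sampleId))
    dt <- data.table::fread(text = txt, header = FALSE, sep = "\t",
                            colClasses = cxCols$colClasses,
                            col.names = cxCols$col.names)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = cxCols$colClasses,
                            col.names = cxCols$col.names)
  }
  if (ncol(dt) != 7L)
    stop("CX report must have 7 tab-separated columns: ", path)
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("unknown strand symbol '%s' at line %d of %s",
                 dt$strand[bad[1L]], bad[1L], path))
  bad <- which(is.na(dt$pos) | is.na(dt$meth) | is.na(dt$unmeth) |
                 dt$meth < 0 | dt$unmeth < 0 |
                 dt$pos != as.integer(dt$pos))
  if (length(bad))
    stop(sprintf("malformed counts or position at line %d of %s",
                 bad[1L], path))
  gr <- GRanges(dt$chrom, IRanges(as.integer(dt$pos), width = 1L),
                strand = dt$strand)
  MethylationProfile(gr, meth = dt$meth, total = dt$meth + dt$unmeth,
                     sampleId = sampleId)
}

#' Write a MethylationProfile as a Bismark CX report
#'
#' Emits one line per site, sorted by chromosome then position, with context
#' and trinucleotide columns looked up in the genome annotations
#' (unknown-context cytosines are written with the literal label
#' `unknown`).
#'
#' @param profile A [MethylationProfile-class].
#' @param annotations Output of [annotateCytosines()] covering every profile
#'   site; a site lacking an annotation is an error.
#' @param path Output file path (`.gz` suffix writes gzip).
#' @return Invisibly, the path.
#' @export
writeCXReport <- function(profile, annotations, path) {
  keys <- .annoKey(profile@sites)
  idx <- match(keys, .annoKey(annotations))
  if (anyNA(idx))
    stop("profile contains ", sum(is.na(idx)),
         " site(s) lacking a cytosine annotation")
  dt <- data.table::data.table(
    chrom = as.character(seqnames(profile@sites)),
    pos = start(profile@sites),
    strand = as.character(strand(profile@sites)),
    meth = profile@meth,
    unmeth = profile@total - profile@meth,
    context = as.character(annotations$context)[idx],
    tri = annotations$subcontext[idx])
  data.table::setorder(dt, chrom, pos)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Keep sites covered by at least `minReads` reads in every sample
#'
#' The standard coverage filter applied before any level-based selection:
#' a site survives only if its total read count reaches `minReads` in every
#' supplied profile (inclusive threshold). The attrition is reported via
#' `message()`.
#'
#' @param profiles A list of [MethylationProfile-class] objects (or a single
#'   profile).
#' @param minReads Minimum total reads per sample (default 5).
#' @return A width-1 `GRanges` of the retained sites (taken from the first
#'   profile), ordered by chromosome and position.
#' @export
filterMinCoverage <- function(profiles, minReads = 5) {
  if (is(profiles, "MethylationProfile"))
    profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  keys <- .annoKey(profiles[[1L]]@sites)
  keep <- profiles[[1L]]@total >= minReads
  for (p in profiles[-1L]) {
    idx <- match(keys, .annoKey(p@sites))
    tot <- rep(0L, length(keys))
    tot[!is.na(idx)] <- p@total[idx[!is.na(idx)]]
    keep <- keep & tot >= minReads
  }
  out <- profiles[[1L]]@sites[keep]
  message(sprintf("coverage filter (>= %d reads in %d sample(s)): %d of %d sites kept",
                  as.integer(minReads), length(profiles), sum(keep),
                  length(keys)))
  out[order(as.factor(seqnames(out)), start(out))]
}

#' Keep sites methylated in the wild type
#'
#' Applies the wild-type methylation filter used throughout the analysis:
#' CpG-context sites are kept when their WT level is at least `cgMin`
#' (default 50%), CHG/CHH sites when at least `noncgMin` (default 25%).
#' For CpCpG sites this filter acts on the external cytosine, which is
#' simply the CHG rule applied to the external position. Unknown-context
#' sites are dropped; sites without WT coverage are excluded with a warning.
#'
#' @param wt WT [MethylationProfile-class].
#' @param siteSet `GRanges` of candidate sites (e.g. from
#'   [filterMinCoverage()]).
#' @param annotations Output of [annotateCytosines()].
#' @param cgMin,noncgMin Inclusive level thresholds for CpG and non-CpG
#'   contexts.
#' @return The subset of `siteSet` passing the filter, with a `context`
#'   metadata column attached.
#' @export
filterWTMethylated <- function(wt, siteSet, annotations,
                               cgMin = 0.50, noncgMin = 0.25) {
  keys <- .annoKey(siteSet)
  aidx <- match(keys, .annoKey(annotations))
  if (anyNA(aidx))
    stop("some sites in 'siteSet' lack a cytosine annotation")
  ctx <- as.character(annotations$context)[aidx]
  lev <- .levelsAtKeys(wt, keys)
  uncovered <- is.na(lev) & ctx != "unknown"
  if (any(uncovered))
    warning(sum(uncovered),
            " site(s) with no WT coverage excluded from the WT filter")
  keep <- !is.na(lev) &
    ((ctx == "CG" & lev >= cgMin) |
       (ctx %in% c("CHG", "CHH") & lev >= noncgMin))
  out <- siteSet[keep]
  mcols(out)$context <- factor(ctx[keep], levels = CONTEXT_LEVELS)
  message(sprintf("WT methylation filter (CG >= %g, non-CG >= %g): %d of %d sites kept",
                  cgMin, noncgMin, length(out), length(siteSet)))
  out
}
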