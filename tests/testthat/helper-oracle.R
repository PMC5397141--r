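## Independent brute-force oracles for context annotation and CpCpG motif
## discovery. These deliberately take a different route from the package:
## the minus strand is handled by building the reverse-complement string and
## mapping match coordinates back, and contexts are classified by regular
## expressions on the extracted trinucleotide.

.oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

.oracleClassify <- function(tri) {
  ifelse(nchar(tri) < 3L | grepl("N", tri), "unknown",
         ifelse(grepl("^CG", tri), "CG",
                ifelse(grepl("^C[ACT]G", tri), "CHG",
                       ifelse(grepl("^C[ACT][ACT]", tri), "CHH",
                              "unknown"))))
}

## One data.frame row per cytosine on either strand, ordered by pos.
oracleAnnotate <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  out <- list()
  fwd <- gregexpr("C", s, fixed = TRUE)[[1L]]
  if (fwd[1L] != -1L) {
    tri <- substr(rep(s, length(fwd)), fwd, fwd + 2L)
    ctx <- .oracleClassify(tri)
    out$fwd <- data.frame(pos = as.integer(fwd), strand = "+", context = ctx,
                          subcontext = ifelse(ctx == "unknown", "unknown",
                                              tri),
                          stringsAsFactors = FALSE)
  }
  rc <- .oracleRevComp(s)
  rev <- gregexpr("C", rc, fixed = TRUE)[[1L]]
  if (rev[1L] != -1L) {
    tri <- substr(rep(rc, length(rev)), rev, rev + 2L)
    ctx <- .oracleClassify(tri)
    out$rev <- data.frame(pos = L - as.integer(rev) + 1L, strand = "-",
                          context = ctx,
                          subcontext = ifelse(ctx == "unknown", "unknown",
                                              tri),
                          stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    return(data.frame(pos = integer(0), strand = character(0),
                      context = character(0), subcontext = character(0)))
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## External-cytosine forward-strand positions of usable CpCpG sites: a CCG
## motif whose internal cytosine has two determinate downstream bases.
oracleCCGExternals <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  fwd <- gregexpr("CCG(?=[ACGT])", s, perl = TRUE)[[1L]]
  fwd <- if (fwd[1L] == -1L) integer(0) else as.integer(fwd)
  rc <- .oracleRevComp(s)
  rev <- gregexpr("CCG(?=[ACGT])", rc, perl = TRUE)[[1L]]
  rev <- if (rev[1L] == -1L) integer(0) else L - as.integer(rev) + 1L
  list(plus = fwd, minus = rev)
}

## Random test sequence with interspersed N runs.
randomSeqWithNs <- function(len, nRuns = 3, runLen = 5) {
  v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (nRuns > 0) {
    starts <- sample(seq_len(max(len - runLen, 1L)), nRuns)
    for (st in starts)
      v[st:min(st + runLen - 1L, len)] <- "N"
  }
  paste(v, collapse = "")
}

annoAsDF <- function(anno) {
  df <- data.frame(pos = GenomicRanges::start(anno),
                   strand = as.character(GenomicRanges::strand(anno)),
                   context = as.character(anno$context),
                   subcontext = anno$subcontext, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
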