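## Hand-built MethylationProfile over explicit sites; levels are encoded as
## meth/total with the requested depth.
makeProfile <- function(chrom, pos, strand, level, total = 10L,
                        sampleId = "test") {
  n <- length(pos)
  total <- rep_len(as.integer(total), n)
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
                               IRanges::IRanges(pos, width = 1L),
                               strand = rep_len(strand, n))
  MethylationProfile(gr, meth = as.integer(round(level * total)),
                     total = total, sampleId = sampleId)
}

## Profile over an annotation set at given true levels, exact counts
## (meth = round(level * total)), i.e. noise-free at the chosen depth.
profileFromAnnotations <- function(anno, levels, total = 10L,
                                   sampleId = "test") {
  n <- length(anno)
  total <- rep_len(as.integer(total), n)
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(anno),
                               IRanges::IRanges(GenomicRanges::start(anno),
                                                width = 1L),
                               strand = GenomicRanges::strand(anno))
  MethylationProfile(gr, meth = as.integer(round(levels * total)),
                     total = total, sampleId = sampleId)
}

## Small deterministic simulation shared by several tests.
smallSimConfig <- function(seed = 7, ...) {
  simulationConfig(seed = seed, chromLengths = c(chr1 = 60000, chr2 = 40000),
                   ...)
}
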