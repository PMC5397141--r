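#' MethylationProfile: per-cytosine methylation counts for one sample
#'
#' Holds, for a single bisulfite sample, the number of methylated and total
#' reads observed at each cytosine. Sites are keyed by (chromosome, 1-based
#' position, strand); strand-symmetric CpG dyads are deliberately kept as two
#' independent sites. The methylation level of a site is
#' `methReads / totalReads`, defined only where `totalReads > 0`.
#'
#' @slot sampleId Single sample identifier.
#' @slot sites Width-1 [GenomicRanges::GRanges] of cytosine positions with
#'   strand `+` or `-`.
#' @slot meth Integer vector of methylated read counts, parallel to `sites`.
#' @slot total Integer vector of total read counts, parallel to `sites`.
#' @seealso [readCXReport()], [sampleReads()], [methLevel()]
#' @export
setClass("MethylationProfile",
         representation(sampleId = "character", sites = "GRanges",
                        meth = "integer", total = "integer"))

setValidity("MethylationProfile", function(object) {
  n <- length(object@sites)
  if (length(object@meth) != n || length(object@total) != n)
    return("'meth' and 'total' must be parallel to 'sites'")
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    return("'sampleId' must be a single non-NA string")
  if (any(GenomicRanges::width(object@sites) != 1L))
    return("'sites' must have width 1")
  if (any(!as.character(GenomicRanges::strand(object@sites)) %in% c("+", "-")))
    return("site strand must be '+' or '-'")
  if (anyNA(object@meth) || anyNA(object@total))
    return("read counts must not be NA")
  if (any(object@meth < 0L) || any(object@total < 0L))
    return("read counts must be non-negative")
  if (any(object@meth > object@total))
    return("methylated reads exceed total reads at some sites")
  TRUE
})

#' Construct a MethylationProfile
#'
#' @param sites Width-1 `GRanges` of cytosine positions (strand `+`/`-`).
#' @param meth,total Integer vectors of methylated and total read counts,
#'   parallel to `sites`.
#' @param sampleId Sample identifier.
#' @return A [MethylationProfile-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2, 3), width = 1),
#'                              strand = c("+", "-"))
#' MethylationProfile(gr, meth = c(3L, 0L), total = c(10L, 0L), "demo")
#' @export
MethylationProfile <- function(sites, meth, total, sampleId = "sample") {
  new("MethylationProfile", sampleId = as.character(sampleId), sites = sites,
      meth = as.integer(meth), total = as.integer(total))
}

#' @describeIn MethylationProfile-class Number of sites in the profile.
#' @param x A `MethylationProfile`.
#' @export
setMethod("length", "MethylationProfile", function(x) length(x@sites))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @describeIn MethylationProfile-class Sample identifier.
#' @export
setMethod("sampleId", "MethylationProfile", function(x) x@sampleId)

#' @export
setGeneric("profileSites", function(x) standardGeneric("profileSites"))

#' @describeIn MethylationProfile-class The site `GRanges` (no counts).
#' @export
setMethod("profileSites", "MethylationProfile", function(x) x@sites)

#' @export
setGeneric("methReads", function(x) standardGeneric("methReads"))

#' @describeIn MethylationProfile-class Methylated read counts.
#' @export
setMethod("methReads", "MethylationProfile", function(x) x@meth)

#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @describeIn MethylationProfile-class Total read counts.
#' @export
setMethod("totalReads", "MethylationProfile", function(x) x@total)

#' @export
setGeneric("methLevel", function(x) standardGeneric("methLevel"))

#' @describeIn MethylationProfile-class Per-site methylation level
#'   (`NA` where the site has no reads).
#' @export
setMethod("methLevel", "MethylationProfile", function(x) {
  lev <- x@meth / x@total
  lev[x@total == 0L] <- NA_real_
  lev
})

setMethod("show", "MethylationProfile", function(object) {
  cov <- object@total > 0L
  cat("MethylationProfile '", object@sampleId, "': ",
      length(object@sites), " sites, ",
      sum(cov), " covered (mean depth ",
      format(mean(object@total), digits = 3), ")\n", sep = "")
  if (any(cov))
    cat("  mean level over covered sites: ",
        format(mean(object@meth[cov] / object@total[cov]), digits = 3),
        "\n", sep = "")
})

## Profile levels/counts looked up at arbitrary keyed positions; NA where the
## profile lacks the site.
.profileIndex <- function(profile, keys) {
  match(keys, .annoKey(profile@sites))
}

.levelsAtKeys <- function(profile, keys) {
  idx <- .profileIndex(profile, keys)
  lev <- rep(NA_real_, length(keys))
  ok <- !is.na(idx)
  tot <- profile@total[idx[ok]]
  lv <- profile@meth[idx[ok]] / tot
  lv[tot == 0L] <- NA_real_
  lev[ok] <- lv
  lev
}
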