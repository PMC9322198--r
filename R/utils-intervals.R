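#' @import GenomicRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols DataFrame
#' @importFrom GenomeInfoDb seqnames seqlengths
NULL

# All public data frames in this package carry genomic intervals as
# chrom/start/end in 0-based half-open (BED) coordinates.  GRanges (1-based
# closed) are used internally for overlap arithmetic only; these two helpers
# are the single conversion point.

#' Convert a BED-style data frame to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); any further columns become metadata columns.
#' @param chrom_sizes optional named integer vector of chromosome lengths.
#' @return a `GRanges` object (1-based closed internally).
#' @export
bed_to_granges <- function(df, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$end <= df$start))
    stop("invalid interval: end <= start")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  }
  gr
}

#' Convert GRanges back to a BED-style data frame
#'
#' @param gr a `GRanges` object.
#' @return data.frame with 0-based half-open `chrom`/`start`/`end` columns
#'   plus any metadata columns.
#' @export
granges_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md)) df <- cbind(df, md)
  rownames(df) <- NULL
  df
}

# findOverlaps without the disjoint-seqlevel warning (query and subject
# legitimately cover different chromosome sets here)
.fo <- function(...) suppressWarnings(GenomicRanges::findOverlaps(...))

# overlap width (bp) between one interval data frame row set and an interval
# set; returns per-row total overlap against the UNION of the subject set.
.overlap_bp <- function(df, subject_df) {
  if (nrow(df) == 0) return(integer(0))
  if (nrow(subject_df) == 0) return(integer(nrow(df)))
  q <- bed_to_granges(df[, c("chrom", "start", "end")])
  s <- GenomicRanges::reduce(bed_to_granges(subject_df[, c("chrom", "start", "end")]))
  cov <- rep(0L, nrow(df))
  hits <- .fo(q, s)
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.integer(agg)
  }
  cov
}

# TRUE per row of df when it overlaps (>= min_bp) any interval in subject_df
.overlaps_any <- function(df, subject_df, min_bp = 1L) {
  .overlap_bp(df, subject_df) >= min_bp
}

# simple percentage helper used by the reporting routines
#' Percentage of a count over a total, rounded to printed precision
#'
#' @param n numerator count(s).
#' @param total denominator.
#' @param digits decimal digits to round to (default 1).
#' @return numeric percentage(s).
#' @export
pct <- function(n, total, digits = 1) {
  round(100 * n / total, digits)
}
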