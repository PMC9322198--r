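# Source-side preparation of the interactome: anchor classification against
# gene models, promoter <-> non-promoter pair selection, and the epigenetic
# enhancer-state call from histone-mark peaks.

#' Classify an anchor against gene models
#'
#' An anchor is a `promoter` when it overlaps (>= 1 bp) any window of
#' `promoter_halfwidth` bp on each side of a TSS; otherwise `genic` when it
#' overlaps any gene body; otherwise `intergenic`.
#'
#' @param anchors data.frame of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param gene_models gene-model table (`gene_id`, `chrom`, `tss`, `start`,
#'   `end`).
#' @param promoter_halfwidth promoter window half-width in bp around the TSS
#'   (default 2500, i.e. TSS +/- 2.5 kb).
#' @return character vector of classes, one per anchor row.  Anchors on
#'   chromosomes absent from the gene models are `intergenic` (a warning is
#'   logged).
#' @export
classify_anchor <- function(anchors, gene_models, promoter_halfwidth = 2500) {
  if (nrow(anchors) == 0) return(character(0))
  unknown <- !(anchors$chrom %in% gene_models$chrom)
  if (any(unknown))
    warning(sum(unknown), " anchor(s) on chromosomes absent from the gene",
            " models; classified intergenic")
  prom <- data.frame(chrom = gene_models$chrom,
                     start = pmax(0L, gene_models$tss - promoter_halfwidth),
                     end = gene_models$tss + promoter_halfwidth)
  bodies <- gene_models[, c("chrom", "start", "end")]
  is_prom <- .overlaps_any(anchors, prom)
  is_genic <- .overlaps_any(anchors, bodies)
  ifelse(is_prom, "promoter", ifelse(is_genic, "genic", "intergenic"))
}

#' Select promoter <-> non-promoter interaction pairs
#'
#' Keeps exactly the anchor pairs with one promoter anchor and one
#' non-promoter (genic or intergenic) anchor, normalising orientation so the
#' promoter is stored first.  Promoter-promoter and nonP-nonP pairs are
#' dropped, with counts reported via message.
#'
#' @param pairs interaction table with left/right anchors: columns `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`, plus `id`, `replicate`,
#'   `pet_count`.
#' @param class1,class2 anchor classes for the left/right anchors (from
#'   [classify_anchor()]).
#' @return data.frame of candidate interactions with the promoter anchor in
#'   `chrom`/`p_start`/`p_end`, the other anchor in
#'   `e_chrom`/`e_start`/`e_end`, and `enhancer_anchor_class`.
#' @export
select_ep_pairs <- function(pairs, class1, class2) {
  p1 <- class1 == "promoter"
  p2 <- class2 == "promoter"
  keep <- xor(p1, p2)
  n_pp <- sum(p1 & p2)
  n_nn <- sum(!p1 & !p2)
  if (n_pp + n_nn > 0)
    message("dropped ", n_pp, " promoter-promoter and ", n_nn,
            " nonpromoter-nonpromoter pair(s)")
  k <- which(keep)
  swap <- p2[k]  # promoter is the right anchor: swap so promoter comes first
  data.frame(
    id = pairs$id[k], replicate = pairs$replicate[k],
    pet_count = pairs$pet_count[k],
    chrom = ifelse(swap, pairs$chrom2[k], pairs$chrom1[k]),
    p_start = ifelse(swap, pairs$start2[k], pairs$start1[k]),
    p_end = ifelse(swap, pairs$end2[k], pairs$end1[k]),
    e_chrom = ifelse(swap, pairs$chrom1[k], pairs$chrom2[k]),
    e_start = ifelse(swap, pairs$start1[k], pairs$start2[k]),
    e_end = ifelse(swap, pairs$end1[k], pairs$end2[k]),
    enhancer_anchor_class = ifelse(swap, class1[k], class2[k]),
    stringsAsFactors = FALSE
  )
}

#' Call the epigenetic state of an enhancer anchor
#'
#' Peaks of each mark are merged (abutting/overlapping runs collapsed) and
#' only merged peaks of length >= `min_mark_len` that touch the anchor
#' (>= 1 bp) qualify.  The anchor is `active` when at least one qualifying
#' H3K4me1 peak and one qualifying H3K27Ac peak additionally overlap each
#' other by >= `min_reciprocal` bp; `poised` when only qualifying H3K4me1 is
#' present; `none` otherwise (such interactions are excluded downstream).
#'
#' @param anchors data.frame of enhancer anchors (`chrom`, `start`, `end`).
#' @param k4me1_peaks,k27ac_peaks peak tables (`chrom`, `start`, `end`).
#' @param min_mark_len minimum merged-peak length in bp (default 300).
#' @param min_reciprocal minimum overlap in bp between the two marks'
#'   qualifying peaks for the `active` call (default 10).
#' @return character vector in `{active, poised, none}`, one per anchor.
#' @export
call_enhancer_state <- function(anchors, k4me1_peaks, k27ac_peaks,
                                min_mark_len = 300, min_reciprocal = 10) {
  if (nrow(anchors) == 0) return(character(0))
  merge_peaks <- function(pk) {
    if (is.null(pk) || nrow(pk) == 0)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    granges_to_bed(GenomicRanges::reduce(
      bed_to_granges(pk[, c("chrom", "start", "end")])))
  }
  k4 <- merge_peaks(k4me1_peaks)
  k4 <- k4[k4$end - k4$start >= min_mark_len, , drop = FALSE]
  k27 <- merge_peaks(k27ac_peaks)
  k27 <- k27[k27$end - k27$start >= min_mark_len, , drop = FALSE]

  agr <- bed_to_granges(anchors[, c("chrom", "start", "end")])
  k4gr <- bed_to_granges(k4)
  k27gr <- bed_to_granges(k27)
  h4 <- .fo(agr, k4gr)
  h27 <- .fo(agr, k27gr)
  has_k4 <- seq_along(agr) %in% S4Vectors::queryHits(h4)

  # active: some K4me1/K27Ac peak pair, both touching the anchor, that
  # co-overlap by >= min_reciprocal bp
  active <- rep(FALSE, length(agr))
  if (length(h4) && length(h27)) {
    cross <- .fo(k4gr, k27gr,
                                         minoverlap = min_reciprocal)
    if (length(cross)) {
      k4_by_anchor <- split(S4Vectors::subjectHits(h4),
                            S4Vectors::queryHits(h4))
      k27_by_anchor <- split(S4Vectors::subjectHits(h27),
                             S4Vectors::queryHits(h27))
      pair_key <- paste(S4Vectors::queryHits(cross),
                        S4Vectors::subjectHits(cross))
      for (a in intersect(names(k4_by_anchor), names(k27_by_anchor))) {
        combos <- expand.grid(k4_by_anchor[[a]], k27_by_anchor[[a]])
        if (any(paste(combos[[1]], combos[[2]]) %in% pair_key))
          active[as.integer(a)] <- TRUE
      }
    }
  }
  ifelse(active, "active", ifelse(has_k4, "poised", "none"))
}

#' Prepare the source-side interactome
#'
#' Runs anchor classification, promoter/non-promoter pair selection and
#' enhancer-state calling, keeping only interactions whose non-promoter
#' anchor carries enhancer marks (`active` or `poised`).  Replicates are
#' pooled; provenance stays in the replicate-prefixed id.
#'
#' @param pairs raw anchor-pair table (see [select_ep_pairs()]).
#' @param gene_models source gene models.
#' @param k4me1_peaks,k27ac_peaks source histone-mark peak tables.
#' @param promoter_halfwidth,min_mark_len,min_reciprocal thresholds, see
#'   [classify_anchor()] and [call_enhancer_state()].
#' @return the filtered interaction table with `enhancer_state` attached.
#' @export
prepare_interactome <- function(pairs, gene_models, k4me1_peaks, k27ac_peaks,
                                promoter_halfwidth = 2500,
                                min_mark_len = 300, min_reciprocal = 10) {
  a1 <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                   end = pairs$end1)
  a2 <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                   end = pairs$end2)
  class1 <- classify_anchor(a1, gene_models, promoter_halfwidth)
  class2 <- classify_anchor(a2, gene_models, promoter_halfwidth)
  ep <- select_ep_pairs(pairs, class1, class2)
  if (nrow(ep) == 0) { ep$enhancer_state <- character(0); return(ep) }
  enh <- data.frame(chrom = ep$e_chrom, start = ep$e_start, end = ep$e_end)
  ep$enhancer_state <- call_enhancer_state(enh, k4me1_peaks, k27ac_peaks,
                                           min_mark_len, min_reciprocal)
  ep[ep$enhancer_state != "none", , drop = FALSE]
}
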