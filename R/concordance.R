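# Concordance of remapped regions with target-genome annotation layers:
# histone-mark peaks, sequence conservation (vs a shuffled null), TADs,
# chromatin-loop datasets, candidate cis-regulatory elements, and in-vivo
# validated enhancer sets.

#' Shuffle regions to matched random positions
#'
#' For every input region, one random region of identical length is drawn
#' uniformly on the same chromosome (length + chromosomal distribution
#' matching).  Null regions may overlap each other but never exceed
#' chromosome bounds.
#'
#' @param regions data.frame `chrom`, `start`, `end`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param seed integer seed; the same seed reproduces the same null set.
#' @return data.frame of null regions, same rows/order as the input.
#' @export
shuffle_regions <- function(regions, chrom_sizes, seed) {
  set.seed(seed)
  len <- regions$end - regions$start
  room <- chrom_sizes[regions$chrom] - len
  if (any(is.na(room)) || any(room < 0)) {
    bad <- which(is.na(room) | room < 0)[1]
    stop(sprintf("region %s:%d-%d does not fit its chromosome",
                 regions$chrom[bad], regions$start[bad], regions$end[bad]))
  }
  start <- floor(stats::runif(nrow(regions), 0, room + 1))
  start <- pmin(as.integer(start), as.integer(room))
  data.frame(chrom = regions$chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# mean per-base score of each region under a bedGraph-style track;
# uncovered bases score 0
region_mean_score <- function(regions, track) {
  if (nrow(regions) == 0) return(numeric(0))
  q <- bed_to_granges(regions[, c("chrom", "start", "end")])
  s <- bed_to_granges(track[, c("chrom", "start", "end")])
  out <- numeric(nrow(regions))
  h <- .fo(q, s)
  if (length(h)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(h)], s[S4Vectors::subjectHits(h)]))
    contrib <- w * track$score[S4Vectors::subjectHits(h)]
    agg <- tapply(contrib, S4Vectors::queryHits(h), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out / (regions$end - regions$start)
}

#' Compare region conservation against a shuffled null
#'
#' Each region is summarised by its mean per-base track score; the two
#' score sets are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param regions data.frame of regions of interest.
#' @param null data.frame of matched null regions (see [shuffle_regions()]).
#' @param track conservation track (`chrom`, `start`, `end`, `score`), per-base
#'   scores in [0, 1]; bases not covered score 0.
#' @return list with `statistic` (W), `p_value`, `region_scores`,
#'   `null_scores`.
#' @export
conservation_compare <- function(regions, null, track) {
  if (nrow(regions) == 0 || nrow(null) == 0)
    stop("conservation_compare: empty region set")
  rs <- region_mean_score(regions, track)
  ns <- region_mean_score(null, track)
  if (all(rs == ns[1]) && all(ns == ns[1])) {
    # fully degenerate tie case: test is uninformative
    return(list(statistic = length(rs) * length(ns) / 2, p_value = 1,
                region_scores = rs, null_scores = ns))
  }
  wt <- suppressWarnings(stats::wilcox.test(rs, ns, alternative = "two.sided",
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       region_scores = rs, null_scores = ns)
}

#' Score enhancer regions against per-tissue histone-mark layers
#'
#' A region is `matched` in a tissue when it overlaps the tissue's H3K4me1
#' layer by at least `min_overlap_bp`.  The state in the target species is
#' `active` when the H3K27Ac layer (where available) is also matched,
#' `poised` when only H3K4me1 matches, and `unknown` when the tissue lacks
#' an H3K27Ac layer.
#'
#' @param enhancers data.frame with `id`, `chrom`, `start`, `end`.
#' @param peak_layers named list (per tissue) of lists with elements
#'   `H3K4me1` (required) and optionally `H3K27Ac`, each a peak table.
#' @param min_overlap_bp match threshold in bp (default 50).
#' @return list with `table` (one row per enhancer x tissue: `id`, `tissue`,
#'   `matched`, `overlap_bp`, `coverage_fraction`, `state_in_human`) and
#'   `summary` (per-tissue matched counts and percentages).
#' @export
mark_concordance <- function(enhancers, peak_layers, min_overlap_bp = 50) {
  rows <- list()
  for (tissue in names(peak_layers)) {
    layer <- peak_layers[[tissue]]
    k4 <- layer$H3K4me1
    stopifnot(!is.null(k4))
    ov <- .overlap_bp(enhancers, k4)
    matched <- ov >= min_overlap_bp
    if (!is.null(layer$H3K27Ac)) {
      ov27 <- .overlap_bp(enhancers, layer$H3K27Ac)
      state <- ifelse(matched & ov27 >= min_overlap_bp, "active",
                      ifelse(matched, "poised", NA_character_))
    } else {
      state <- ifelse(matched, "unknown", NA_character_)
    }
    rows[[tissue]] <- data.frame(
      id = enhancers$id, tissue = tissue, matched = matched,
      overlap_bp = ov,
      coverage_fraction = ov / (enhancers$end - enhancers$start),
      state_in_human = state, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(names(peak_layers), function(tissue) {
    m <- tab$matched[tab$tissue == tissue]
    data.frame(tissue = tissue, n = length(m), matched = sum(m),
               matched_pct = pct(sum(m), length(m)),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}

#' Cumulative unique-match curve over tissues
#'
#' Tissues are ordered by ascending per-tissue matched count; the curve
#' value at k is the number of unique regions matched in at least one of
#' the first k tissues.
#'
#' @param matched_sets named list: per tissue, the ids matched there.
#' @return data.frame `tissue`, `n_matched`, `cumulative_unique`.
#' @export
cumulative_match <- function(matched_sets) {
  ord <- order(lengths(matched_sets),
               names(matched_sets))  # deterministic tie-break by name
  acc <- character(0)
  cum <- integer(length(ord))
  for (i in seq_along(ord)) {
    acc <- union(acc, matched_sets[[ord[i]]])
    cum[i] <- length(acc)
  }
  data.frame(tissue = names(matched_sets)[ord],
             n_matched = lengths(matched_sets)[ord],
             cumulative_unique = cum, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assign remapped interactions to TADs
#'
#' Per dataset, a record is `intra` when some single TAD fully contains
#' both anchors, `inter` when each anchor is fully inside some TAD but no
#' single TAD holds both, and `outside` otherwise.
#'
#' @param hmslris master remapped table restricted to `P_plus_E` rows.
#' @param tad_sets named list of TAD tables (`chrom`, `start`, `end`).
#' @return list with `table` (`id`, `dataset`, `status`) and `summary`
#'   (per-dataset counts plus the union count of records intra in >= 1
#'   dataset).
#' @export
tad_call <- function(hmslris, tad_sets) {
  within_ids <- function(anchor_df, tads) {
    # list: per anchor, indices of TADs fully containing it
    out <- rep(list(integer(0)), nrow(anchor_df))
    if (nrow(tads) == 0) return(out)
    h <- .fo(
      bed_to_granges(anchor_df), bed_to_granges(tads[, c("chrom", "start", "end")]),
      type = "within")
    sp <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    for (a in names(sp)) out[[as.integer(a)]] <- sp[[a]]
    out
  }
  p_df <- data.frame(chrom = hmslris$p_chrom, start = hmslris$p_start,
                     end = hmslris$p_end)
  e_df <- data.frame(chrom = hmslris$e_chrom, start = hmslris$e_start,
                     end = hmslris$e_end)
  rows <- list()
  for (ds in names(tad_sets)) {
    pw <- within_ids(p_df, tad_sets[[ds]])
    ew <- within_ids(e_df, tad_sets[[ds]])
    status <- vapply(seq_len(nrow(hmslris)), function(i) {
      if (length(intersect(pw[[i]], ew[[i]]))) "intra"
      else if (length(pw[[i]]) && length(ew[[i]])) "inter"
      else "outside"
    }, character(1))
    rows[[ds]] <- data.frame(id = hmslris$id, dataset = ds, status = status,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  intra_any <- unique(tab$id[tab$status == "intra"])
  summ <- do.call(rbind, lapply(names(tad_sets), function(ds) {
    st <- tab$status[tab$dataset == ds]
    data.frame(dataset = ds, intra = sum(st == "intra"),
               inter = sum(st == "inter"), outside = sum(st == "outside"),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ, intra_any = intra_any,
       intra_any_pct = pct(length(intra_any), nrow(hmslris)))
}

#' Count remapped interactions represented in loop datasets
#'
#' A record is represented in a dataset when some loop's two anchors
#' overlap the record's promoter and enhancer respectively (>= `min_bp`
#' each), in either left/right orientation.  Records found in more than one
#' dataset are counted once in the deduplicated total.
#'
#' @param hmslris master remapped table restricted to `P_plus_E` rows.
#' @param loop_sets named list of BEDPE-style loop tables.
#' @param min_bp per-anchor overlap threshold in bp (default 1).
#' @return list with per-dataset represented id sets, per-dataset counts
#'   and percentages (of the `P_plus_E` count), and the deduplicated union.
#' @export
loop_representation <- function(hmslris, loop_sets, min_bp = 1L) {
  n <- nrow(hmslris)
  p_gr <- bed_to_granges(data.frame(chrom = hmslris$p_chrom,
                                    start = hmslris$p_start,
                                    end = hmslris$p_end))
  e_gr <- bed_to_granges(data.frame(chrom = hmslris$e_chrom,
                                    start = hmslris$e_start,
                                    end = hmslris$e_end))
  rep_sets <- list()
  for (ds in names(loop_sets)) {
    lp <- loop_sets[[ds]]
    a_gr <- bed_to_granges(data.frame(chrom = lp$chrom1, start = lp$start1,
                                      end = lp$end1))
    b_gr <- bed_to_granges(data.frame(chrom = lp$chrom2, start = lp$start2,
                                      end = lp$end2))
    pair_hits <- function(rec_gr, loop_gr) {
      h <- .fo(rec_gr, loop_gr, minoverlap = min_bp)
      paste(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
    }
    same <- intersect(pair_hits(p_gr, a_gr), pair_hits(e_gr, b_gr))
    swapped <- intersect(pair_hits(p_gr, b_gr), pair_hits(e_gr, a_gr))
    idx <- unique(as.integer(sub(" .*", "", c(same, swapped))))
    rep_sets[[ds]] <- hmslris$id[idx]
  }
  union_ids <- unique(unlist(rep_sets, use.names = FALSE))
  summ <- do.call(rbind, lapply(names(rep_sets), function(ds)
    data.frame(dataset = ds, represented = length(rep_sets[[ds]]),
               represented_pct = pct(length(rep_sets[[ds]]), n, 2),
               stringsAsFactors = FALSE)))
  list(sets = rep_sets, summary = summ,
       total_unique = length(union_ids),
       total_unique_pct = pct(length(union_ids), n, 2))
}

#' Overlap enhancers with candidate cis-regulatory elements
#'
#' @param enhancers data.frame `id`, `chrom`, `start`, `end`.
#' @param ccres cCRE table (`chrom`, `start`, `end`, `ccre_id`, `subclass`);
#'   one element may carry several subclass labels across rows.
#' @return list with the hit table (enhancer x cCRE, >= 1 bp), the overall
#'   overlap fraction, and per-subclass tallies (fraction of
#'   cCRE-overlapping enhancers touching each subclass).
#' @export
ccre_overlap <- function(enhancers, ccres) {
  q <- bed_to_granges(enhancers[, c("chrom", "start", "end")])
  if (nrow(ccres) == 0) {
    return(list(table = data.frame(id = character(0), ccre_id = character(0),
                                   subclass = character(0)),
                n_overlapping = 0L, overlap_pct = 0,
                per_subclass = data.frame(subclass = character(0),
                                          n = integer(0), fraction = numeric(0))))
  }
  s <- bed_to_granges(ccres[, c("chrom", "start", "end")])
  h <- .fo(q, s)
  tab <- data.frame(id = enhancers$id[S4Vectors::queryHits(h)],
                    ccre_id = ccres$ccre_id[S4Vectors::subjectHits(h)],
                    subclass = ccres$subclass[S4Vectors::subjectHits(h)],
                    stringsAsFactors = FALSE)
  hit_ids <- unique(tab$id)
  per_sub <- if (nrow(tab)) {
    agg <- tapply(tab$id, tab$subclass, function(x) length(unique(x)))
    data.frame(subclass = names(agg), n = as.integer(agg),
               fraction = as.numeric(agg) / length(hit_ids),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(subclass = character(0), n = integer(0),
                    fraction = numeric(0))
  list(table = tab, n_overlapping = length(hit_ids),
       overlap_pct = pct(length(hit_ids), nrow(enhancers)),
       per_subclass = per_sub)
}

#' Overlap enhancers with an in-vivo validated enhancer set
#'
#' @param enhancers data.frame `id`, `chrom`, `start`, `end`.
#' @param vista validated-enhancer table (`chrom`, `start`, `end`,
#'   `element_id`, `label` in {positive, negative}).
#' @return list with the positive-hit table, positive hit count, and the
#'   negative-overlap table reported separately.
#' @export
vista_overlap <- function(enhancers, vista) {
  hit_table <- function(sub) {
    if (nrow(sub) == 0)
      return(data.frame(id = character(0), element_id = character(0)))
    h <- .fo(
      bed_to_granges(enhancers[, c("chrom", "start", "end")]),
      bed_to_granges(sub[, c("chrom", "start", "end")]))
    data.frame(id = enhancers$id[S4Vectors::queryHits(h)],
               element_id = sub$element_id[S4Vectors::subjectHits(h)],
               stringsAsFactors = FALSE)
  }
  pos <- hit_table(vista[vista$label == "positive", , drop = FALSE])
  neg <- hit_table(vista[vista$label == "negative", , drop = FALSE])
  list(positive = pos, n_positive_elements = length(unique(pos$element_id)),
       n_enhancers_hit = length(unique(pos$id)), negative = neg)
}
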