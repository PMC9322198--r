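# Disease-side overlays: GWAS risk variants inside remapped enhancers,
# PWM binding-site disruption calls, CNV overlap, enhancer-only disruption
# detection, and case/control hypergeometric enrichment.

#' Construct a position probability matrix motif
#'
#' @param motif_id,tf_name identifiers.
#' @param matrix numeric matrix, one row per position, columns A/C/G/T,
#'   rows summing to 1 (tolerance 1e-9).
#' @return a `pwm_motif` object.
#' @export
pwm_motif <- function(motif_id, tf_name, matrix) {
  stopifnot(ncol(matrix) == 4, all(matrix >= 0))
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("PWM ", motif_id, ": rows must sum to 1")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_name = tf_name, matrix = matrix),
            class = "pwm_motif")
}

#' Find risk variants inside remapped enhancers
#'
#' Variants passing the posterior-probability filter (`ppa > ppa_min`,
#' strictly) are intersected with the enhancer intervals; each hit is
#' connected to the gene(s) of the interaction's promoter annotation.  One
#' variant may hit several enhancers and vice versa.
#'
#' @param variants data.frame `rsid`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `trait`, `ppa`.
#' @param hmslris master remapped table restricted to rows with a mapped
#'   enhancer; promoter-side gene annotation in column `connected_gene`
#'   (comma-separated ids, may be empty).
#' @param ppa_min posterior-probability threshold (default 0.01; variants
#'   at exactly the threshold are excluded).
#' @param ccres optional target-side cCRE table; adds an `in_ccre` flag.
#' @return hit table: `rsid`, `trait`, `ppa`, `id` (interaction),
#'   `enhancer_chrom/start/end`, `connected_gene`, `in_ccre`.
#' @export
variants_in_enhancers <- function(variants, hmslris, ppa_min = 0.01,
                                  ccres = NULL) {
  v <- variants[variants$ppa > ppa_min, , drop = FALSE]
  enh <- hmslris[!is.na(hmslris$e_chrom), , drop = FALSE]
  # a 1-based variant position p falls in [start, end) iff start <= p-1 < end
  vdf <- data.frame(chrom = v$chrom, start = v$pos - 1L, end = v$pos)
  hits <- if (nrow(v) && nrow(enh)) {
    h <- .fo(
      bed_to_granges(vdf),
      bed_to_granges(data.frame(chrom = enh$e_chrom, start = enh$e_start,
                                end = enh$e_end)))
    data.frame(vi = S4Vectors::queryHits(h), ei = S4Vectors::subjectHits(h))
  } else data.frame(vi = integer(0), ei = integer(0))
  out <- data.frame(
    rsid = v$rsid[hits$vi], trait = v$trait[hits$vi], ppa = v$ppa[hits$vi],
    id = enh$id[hits$ei],
    enhancer_chrom = enh$e_chrom[hits$ei],
    enhancer_start = enh$e_start[hits$ei],
    enhancer_end = enh$e_end[hits$ei],
    connected_gene = if ("connected_gene" %in% names(enh))
      enh$connected_gene[hits$ei] else NA_character_,
    stringsAsFactors = FALSE
  )
  out$in_ccre <- if (!is.null(ccres) && nrow(out))
    .overlaps_any(data.frame(chrom = out$enhancer_chrom,
                             start = out$enhancer_start,
                             end = out$enhancer_end), ccres)
  else if (nrow(out)) NA else logical(0)
  out <- out[order(out$rsid, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# log2 odds score of one window sequence (character vector of bases)
# against a PWM with pseudocount and uniform 0.25 background
.pwm_window_score <- function(bases, mat, pseudocount) {
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(-Inf)  # ambiguous base: window not scoreable
  p <- mat[cbind(seq_along(idx), idx)]
  sum(log2((p + pseudocount) / 0.25))
}

#' Score binding-site disruption by a variant
#'
#' Every placement of the motif window covering the variant position is
#' scored on both strands, for the reference and the alternate sequence;
#' the per-allele best scores are compared.  Score of a window is
#' `sum log2((p_base + pseudocount) / 0.25)` in bits.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `rsid`.
#' @param genome a `Biostrings::DNAStringSet` (or named character vector)
#'   of target chromosome sequences.
#' @param pwm a `pwm_motif`.
#' @param effect_threshold bits of best-score change needed to call a site
#'   `lost` (delta <= -threshold) or `gained` (delta >= threshold);
#'   default 1.
#' @param pseudocount probability pseudocount (default 0.01).
#' @return list: `rsid`, `motif_id`, `best_ref_score`, `best_alt_score`,
#'   `delta`, `effect`, and the `strand`/`offset` (0-based window start) of
#'   the best alternate window.
#' @export
score_motif_disruption <- function(variant, genome, pwm,
                                   effect_threshold = 1, pseudocount = 0.01) {
  chrom_seq <- if (inherits(genome, "DNAStringSet"))
    as.character(genome[[variant$chrom]]) else genome[[variant$chrom]]
  L <- nrow(pwm$matrix)
  pos <- as.integer(variant$pos)
  ref_base <- substr(chrom_seq, pos, pos)
  if (ref_base != variant$ref)
    stop(sprintf("reference allele mismatch at %s:%d (genome %s, variant %s)",
                 variant$chrom, pos, ref_base, variant$ref))
  starts <- (pos - L + 1L):pos
  starts <- starts[starts >= 1L & starts + L - 1L <= nchar(chrom_seq)]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- function(allele) {
    best_score <- -Inf; best_strand <- NA_character_; best_off <- NA_integer_
    for (s in starts) {
      win <- strsplit(substr(chrom_seq, s, s + L - 1L), "")[[1]]
      win[pos - s + 1L] <- allele
      fwd <- .pwm_window_score(win, pwm$matrix, pseudocount)
      rc <- .pwm_window_score(rev(unname(comp[win])), pwm$matrix, pseudocount)
      if (fwd > best_score) { best_score <- fwd; best_strand <- "+"; best_off <- s - 1L }
      if (rc > best_score) { best_score <- rc; best_strand <- "-"; best_off <- s - 1L }
    }
    list(score = best_score, strand = best_strand, offset = best_off)
  }
  r <- best(variant$ref)
  a <- best(variant$alt)
  delta <- a$score - r$score
  effect <- if (delta <= -effect_threshold) "lost"
            else if (delta >= effect_threshold) "gained" else "neutral"
  list(rsid = variant$rsid, motif_id = pwm$motif_id,
       best_ref_score = r$score, best_alt_score = a$score, delta = delta,
       effect = effect, strand = a$strand, offset = a$offset)
}

#' Overlap CNVs with remapped interactions
#'
#' @param cnvs CNV table: `chrom`, `start`, `end`, `cnv_type` (gain/loss),
#'   `cohort` (case/control), `phenotype`, `subject_id`,
#'   `pathogenicity_class` (carried from input, never computed here).
#' @param hmslris master remapped table; rows with a mapped enhancer and/or
#'   promoter are considered.
#' @return one row per (CNV, interaction) pair with >= 1 bp overlap of
#'   either anchor: CNV columns plus `id`, `overlaps_enhancer`,
#'   `overlaps_promoter`.
#' @export
cnv_overlap <- function(cnvs, hmslris) {
  if (nrow(cnvs) == 0 || nrow(hmslris) == 0)
    return(data.frame(cnv_row = integer(0), id = character(0),
                      overlaps_enhancer = logical(0),
                      overlaps_promoter = logical(0)))
  cgr <- bed_to_granges(cnvs[, c("chrom", "start", "end")])
  anchor_hits <- function(chrom, start, end) {
    present <- !is.na(chrom)
    if (!any(present)) return(data.frame(ci = integer(0), ri = integer(0)))
    sub <- data.frame(chrom = chrom[present], start = start[present],
                      end = end[present])
    h <- .fo(cgr, bed_to_granges(sub))
    data.frame(ci = S4Vectors::queryHits(h),
               ri = which(present)[S4Vectors::subjectHits(h)])
  }
  eh <- anchor_hits(hmslris$e_chrom, hmslris$e_start, hmslris$e_end)
  ph <- anchor_hits(hmslris$p_chrom, hmslris$p_start, hmslris$p_end)
  key_all <- unique(rbind(eh, ph))
  if (nrow(key_all) == 0)
    return(data.frame(cnv_row = integer(0), id = character(0),
                      overlaps_enhancer = logical(0),
                      overlaps_promoter = logical(0)))
  ek <- paste(eh$ci, eh$ri); pk <- paste(ph$ci, ph$ri)
  kk <- paste(key_all$ci, key_all$ri)
  out <- cbind(
    cnvs[key_all$ci, , drop = FALSE],
    data.frame(cnv_row = key_all$ci, id = hmslris$id[key_all$ri],
               overlaps_enhancer = kk %in% ek,
               overlaps_promoter = kk %in% pk, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$cnv_row, out$id), , drop = FALSE]
}

#' Keep enhancer-only CNV disruptions
#'
#' Restricts a [cnv_overlap()] table to rows where the CNV hits the
#' enhancer but not the promoter of the same interaction.  When the control
#' cohort is supplied, a `case_exclusive` flag marks case CNVs with no
#' same-type control CNV at >= `reciprocal` reciprocal overlap.
#'
#' @param overlap_table output of [cnv_overlap()].
#' @param control_cnvs optional control-cohort CNV table.
#' @param reciprocal reciprocal-overlap fraction for the exclusivity check
#'   (default 0.5).
#' @return the filtered table, with `case_exclusive` when applicable.
#' @export
enhancer_only_disruptions <- function(overlap_table, control_cnvs = NULL,
                                      reciprocal = 0.5) {
  keep <- overlap_table$overlaps_enhancer & !overlap_table$overlaps_promoter
  out <- overlap_table[keep, , drop = FALSE]
  if (!is.null(control_cnvs) && nrow(out)) {
    excl <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      ctrl <- control_cnvs[control_cnvs$chrom == out$chrom[i] &
                             control_cnvs$cnv_type == out$cnv_type[i], ,
                           drop = FALSE]
      if (nrow(ctrl) == 0) { excl[i] <- TRUE; next }
      ov <- pmin(ctrl$end, out$end[i]) - pmax(ctrl$start, out$start[i])
      len_case <- out$end[i] - out$start[i]
      len_ctrl <- ctrl$end - ctrl$start
      mirrored <- any(ov >= reciprocal * len_case & ov >= reciprocal * len_ctrl)
      excl[i] <- !mirrored
    }
    out$case_exclusive <- excl
  }
  out
}

#' Hypergeometric enrichment of case CNVs in remapped interactions
#'
#' Universe: all CNVs of both cohorts (N); successes: CNVs overlapping at
#' least one interaction anchor (K); draws: the case cohort (n); observed:
#' case CNVs overlapping (k).  p = upper-tail P(X >= k).
#'
#' @param case_cnvs,control_cnvs CNV tables.
#' @param hmslris master remapped table.
#' @return list `k`, `n`, `K`, `N`, `p_value`, `method`.
#' @export
hypergeometric_enrichment <- function(case_cnvs, control_cnvs, hmslris) {
  stopifnot(nrow(case_cnvs) > 0, nrow(control_cnvs) > 0)
  regions <- rbind(
    stats::na.omit(data.frame(chrom = hmslris$e_chrom,
                              start = hmslris$e_start, end = hmslris$e_end)),
    stats::na.omit(data.frame(chrom = hmslris$p_chrom,
                              start = hmslris$p_start, end = hmslris$p_end)))
  case_hit <- .overlaps_any(case_cnvs, regions)
  ctrl_hit <- .overlaps_any(control_cnvs, regions)
  k <- sum(case_hit); n <- nrow(case_cnvs)
  K <- k + sum(ctrl_hit); N <- n + nrow(control_cnvs)
  if (K == 0 || K == N) {
    message("degenerate margins (K = ", K, ", N = ", N, "): p = 1")
    p <- 1
  } else {
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  list(k = k, n = n, K = K, N = N, p_value = p,
       method = "hypergeometric upper tail")
}

#' Join connected genes to gene-disease panel tables
#'
#' Left join of the interaction-connected genes onto one or more panel
#' tables; genes absent from a panel get confidence `unknown`, and multiple
#' panel rows per gene are all preserved.
#'
#' @param genes character vector of gene ids.
#' @param panel_tables named list of panel data.frames with columns `gene`
#'   and `confidence`.
#' @return data.frame `gene`, `panel`, `confidence`.
#' @export
gene_panel_join <- function(genes, panel_tables) {
  out <- list()
  for (panel in names(panel_tables)) {
    tab <- panel_tables[[panel]]
    m <- merge(data.frame(gene = genes, stringsAsFactors = FALSE),
               tab[, c("gene", "confidence")], by = "gene", all.x = TRUE)
    m$confidence[is.na(m$confidence)] <- "unknown"
    m$panel <- panel
    out[[panel]] <- m[, c("gene", "panel", "confidence")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene, res$panel, res$confidence), , drop = FALSE]
}
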