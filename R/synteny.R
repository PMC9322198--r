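# Synteny classification of remapped interactions and annotation of the
# resulting target-genome regions.
#
# Five outcome classes partition the input interactions:
#   P_plus_E - both anchors remap to the same target chromosome
#   split    - both remap, but to different chromosomes
#   E_only   - only the enhancer anchor remaps
#   P_only   - only the promoter anchor remaps
#   lost     - neither anchor remaps

SYNTENY_CLASSES <- c("P_plus_E", "split", "E_only", "P_only", "lost")

#' Combine two liftover outcomes into a synteny class
#'
#' @param p_mapped,e_mapped logical vectors: did the promoter/enhancer
#'   anchor map (at the shared min_match)?
#' @param p_chrom,e_chrom target chromosomes (NA when unmapped).
#' @return character vector of synteny classes.
#' @export
classify_pair <- function(p_mapped, e_mapped, p_chrom, e_chrom) {
  ifelse(p_mapped & e_mapped,
         ifelse(p_chrom == e_chrom, "P_plus_E", "split"),
         ifelse(e_mapped, "E_only", ifelse(p_mapped, "P_only", "lost")))
}

#' Remap an interaction table and classify each interaction
#'
#' Lifts both anchors of every interaction through the chain set and
#' assigns the synteny class.
#'
#' @param interactions interaction table (from [prepare_interactome()] or
#'   the generator): `id`, `replicate`, `pet_count`, `enhancer_state`,
#'   promoter anchor `chrom`/`p_start`/`p_end`, enhancer anchor
#'   `e_chrom`/`e_start`/`e_end`.
#' @param chains list of `chain_alignment` objects.
#' @param min_match minimum mapped-base fraction (default 0.5).
#' @return the master remapped table: one row per input interaction with
#'   target coordinates (`p_chrom`/`p_start`/`p_end`,
#'   `e_chrom`/`e_start`/`e_end`, NA where unmapped), per-anchor mapped
#'   fractions, and `synteny_class`.
#' @export
map_interactions <- function(interactions, chains, min_match = 0.5) {
  p <- liftover_intervals(
    data.frame(chrom = interactions$chrom, start = interactions$p_start,
               end = interactions$p_end), chains, min_match)
  e <- liftover_intervals(
    data.frame(chrom = interactions$e_chrom, start = interactions$e_start,
               end = interactions$e_end), chains, min_match)
  cls <- classify_pair(p$status == "mapped", e$status == "mapped",
                       p$t_chrom, e$t_chrom)
  data.frame(
    id = interactions$id, replicate = interactions$replicate,
    pet_count = interactions$pet_count,
    enhancer_state = interactions$enhancer_state,
    synteny_class = cls,
    p_chrom = p$t_chrom, p_start = p$t_start, p_end = p$t_end,
    p_fraction = p$mapped_fraction,
    e_chrom = e$t_chrom, e_start = e$t_start, e_end = e$t_end,
    e_fraction = e$mapped_fraction,
    stringsAsFactors = FALSE
  )
}

#' Flag redundant remapped interactions
#'
#' Two records (both-anchors class only) are linked when their promoter
#' intervals reciprocally overlap by more than `frac` of each interval's
#' length AND their enhancer intervals do likewise; groups are the connected
#' components of this relation, with the first member of each group marked
#' as its representative.
#'
#' @param hmslris master remapped table restricted to `P_plus_E` rows.
#' @param frac reciprocal-overlap fraction (default 0.5, strict `>`).
#' @return data.frame `id`, `redundant_group_id`, `is_primary`.
#' @export
flag_redundant <- function(hmslris, frac = 0.5) {
  n <- nrow(hmslris)
  if (n == 0)
    return(data.frame(id = character(0), redundant_group_id = integer(0),
                      is_primary = logical(0)))
  linked_pairs <- function(chrom, start, end) {
    gr <- bed_to_granges(data.frame(chrom = chrom, start = start, end = end))
    h <- .fo(gr, gr)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    if (!length(qi)) return(cbind(integer(0), integer(0)))
    ov <- pmin(end[qi], end[si]) - pmax(start[qi], start[si])
    ok <- ov > frac * (end[qi] - start[qi]) & ov > frac * (end[si] - start[si])
    cbind(qi[ok], si[ok])
  }
  lp <- linked_pairs(hmslris$p_chrom, hmslris$p_start, hmslris$p_end)
  le <- linked_pairs(hmslris$e_chrom, hmslris$e_start, hmslris$e_end)
  both <- merge(data.frame(a = lp[, 1], b = lp[, 2]),
                data.frame(a = le[, 1], b = le[, 2]))
  # connected components by repeated label propagation
  comp <- seq_len(n)
  if (nrow(both)) {
    repeat {
      new_comp <- comp
      m <- pmin(comp[both$a], comp[both$b])
      new_comp[both$a] <- pmin(new_comp[both$a], m)
      new_comp[both$b] <- pmin(new_comp[both$b], m)
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
  }
  grp <- match(comp, sort(unique(comp)))
  data.frame(id = hmslris$id, redundant_group_id = grp,
             is_primary = !duplicated(grp), stringsAsFactors = FALSE)
}

#' Annotate a target-genome region against gene models
#'
#' Priority order: `promoter` (TSS +/- `promoter_halfwidth`) > `exonic` >
#' `intronic` > `intergenic`; the first matching category wins and
#' `gene_ids` lists all genes supporting it.  Overlap is strandless.
#' Without exon structure in the gene models, any within-body overlap that
#' is not promoter counts as `intronic`.
#'
#' @param regions data.frame of intervals (`chrom`, `start`, `end`).
#' @param gene_models target gene models (`gene_id`, `chrom`, `tss`,
#'   `start`, `end`, optional comma-separated `exon_starts`/`exon_ends`).
#' @param promoter_halfwidth promoter window half-width (default 2500 bp).
#' @return data.frame `category`, `gene_ids` (comma-separated), `intragenic`
#'   (>= 1 bp overlap with any gene body).
#' @export
annotate_region <- function(regions, gene_models, promoter_halfwidth = 2500) {
  n <- nrow(regions)
  if (n == 0)
    return(data.frame(category = character(0), gene_ids = character(0),
                      intragenic = logical(0)))
  hits_genes <- function(feat) {
    # feat: data.frame chrom/start/end/gene_id; returns list of gene-id sets
    out <- vector("list", n)
    if (nrow(feat) == 0) return(out)
    h <- .fo(
      bed_to_granges(regions[, c("chrom", "start", "end")]),
      bed_to_granges(feat[, c("chrom", "start", "end")]))
    for (i in seq_along(h))
      out[[S4Vectors::queryHits(h)[i]]] <-
        union(out[[S4Vectors::queryHits(h)[i]]],
              feat$gene_id[S4Vectors::subjectHits(h)[i]])
    out
  }
  prom <- data.frame(chrom = gene_models$chrom,
                     start = pmax(0L, gene_models$tss - promoter_halfwidth),
                     end = gene_models$tss + promoter_halfwidth,
                     gene_id = gene_models$gene_id)
  body <- gene_models[, c("chrom", "start", "end", "gene_id")]
  exons <- if (all(c("exon_starts", "exon_ends") %in% names(gene_models))) {
    es <- strsplit(as.character(gene_models$exon_starts), ",")
    ee <- strsplit(as.character(gene_models$exon_ends), ",")
    data.frame(
      chrom = rep(gene_models$chrom, lengths(es)),
      start = as.integer(unlist(es)), end = as.integer(unlist(ee)),
      gene_id = rep(gene_models$gene_id, lengths(es)))
  } else body[0, ]
  g_prom <- hits_genes(prom)
  g_exon <- hits_genes(exons)
  g_body <- hits_genes(body)
  category <- character(n); gene_ids <- character(n)
  for (i in seq_len(n)) {
    if (length(g_prom[[i]])) {
      category[i] <- "promoter"; ids <- g_prom[[i]]
    } else if (length(g_exon[[i]])) {
      category[i] <- "exonic"; ids <- g_exon[[i]]
    } else if (length(g_body[[i]])) {
      category[i] <- "intronic"; ids <- g_body[[i]]
    } else {
      category[i] <- "intergenic"; ids <- character(0)
    }
    gene_ids[i] <- paste(sort(ids), collapse = ",")
  }
  data.frame(category = category, gene_ids = gene_ids,
             intragenic = lengths(g_body) > 0, stringsAsFactors = FALSE)
}

#' Does a remapped interaction span other genes?
#'
#' TRUE when the genomic span between the enhancer and promoter intervals
#' contains at least one complete gene other than the promoter's own
#' gene(s), or when the enhancer lies inside a gene different from the
#' promoter's gene(s).
#'
#' @param hmslris master remapped table restricted to `P_plus_E` rows.
#' @param gene_models target gene models.
#' @param promoter_halfwidth promoter window half-width used to identify
#'   the promoter's own gene(s).
#' @return logical vector, one per row.
#' @export
spans_multiple_genes <- function(hmslris, gene_models,
                                 promoter_halfwidth = 2500) {
  n <- nrow(hmslris)
  if (n == 0) return(logical(0))
  p_ann <- annotate_region(
    data.frame(chrom = hmslris$p_chrom, start = hmslris$p_start,
               end = hmslris$p_end), gene_models, promoter_halfwidth)
  own <- strsplit(p_ann$gene_ids, ",")
  e_ann <- annotate_region(
    data.frame(chrom = hmslris$e_chrom, start = hmslris$e_start,
               end = hmslris$e_end), gene_models, promoter_halfwidth)
  e_host <- strsplit(e_ann$gene_ids, ",")
  out <- logical(n)
  for (i in seq_len(n)) {
    span_lo <- min(hmslris$p_start[i], hmslris$e_start[i])
    span_hi <- max(hmslris$p_end[i], hmslris$e_end[i])
    inside <- gene_models$chrom == hmslris$p_chrom[i] &
      gene_models$start >= span_lo & gene_models$end <= span_hi
    intervening <- setdiff(gene_models$gene_id[inside], own[[i]])
    host_other <- e_ann$intragenic[i] &&
      length(setdiff(e_host[[i]], own[[i]])) > 0
    out[i] <- length(intervening) > 0 || host_other
  }
  out
}

#' Tabulate synteny classes
#'
#' @param hmslris master remapped table.
#' @param by optional grouping column (e.g. `enhancer_state`).
#' @return named integer vector over the five classes (or a matrix when
#'   grouped); classes always sum to the number of input rows.
#' @export
synteny_class_counts <- function(hmslris, by = NULL) {
  f <- factor(hmslris$synteny_class, levels = SYNTENY_CLASSES)
  if (is.null(by)) table(f) else table(hmslris[[by]], f)
}
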