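# End-to-end orchestration: read the input layers, run the source-side
# preparation, liftover + synteny classification, concordance scoring and
# disease overlays, and write deterministic TSV outputs plus a run
# manifest.

#' Pipeline configuration
#'
#' @param input_dir directory holding the input layout written by
#'   [write_world()] (or equivalently structured real data).
#' @param output_dir directory for stage outputs (created if absent).
#' @param min_match liftover minimum mapped-base fraction.
#' @param promoter_halfwidth promoter window half-width (bp).
#' @param min_mark_len,min_reciprocal enhancer-state thresholds (bp).
#' @param min_overlap_bp histone-mark concordance threshold (bp).
#' @param ppa_min posterior-probability cutoff for risk variants.
#' @param effect_threshold motif-disruption threshold (bits).
#' @param redundancy_frac reciprocal-overlap fraction for redundancy
#'   flagging.
#' @param loop_overlap_bp per-anchor loop overlap threshold (bp).
#' @param seed seed for the shuffled nulls.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            min_match = 0.5, promoter_halfwidth = 2500,
                            min_mark_len = 300, min_reciprocal = 10,
                            min_overlap_bp = 50, ppa_min = 0.01,
                            effect_threshold = 1, redundancy_frac = 0.5,
                            loop_overlap_bp = 1, seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 min_match = min_match,
                 promoter_halfwidth = promoter_halfwidth,
                 min_mark_len = min_mark_len,
                 min_reciprocal = min_reciprocal,
                 min_overlap_bp = min_overlap_bp, ppa_min = ppa_min,
                 effect_threshold = effect_threshold,
                 redundancy_frac = redundancy_frac,
                 loop_overlap_bp = loop_overlap_bp, seed = as.integer(seed)),
            class = "pipeline_config")
}

.required_inputs <- c("source.chrom.sizes", "target.chrom.sizes",
                      "alignment.chain", "genes_source.tsv",
                      "genes_target.tsv", "interactions.bedpe",
                      "peaks_source_H3K4me1.bed", "conservation.bedgraph")

#' Run the full remapping and annotation pipeline
#'
#' Stages: source-side preparation (anchor classification, pair selection,
#' enhancer-state calling), liftover and synteny classification, redundancy
#' flagging and region annotation, concordance scoring (marks, TADs, loops,
#' conservation vs shuffled null, cCREs, validated enhancers), and disease
#' overlays (risk variants, motif disruption, CNV overlap and enrichment).
#' Outputs are written with stable filenames; a manifest records the seed,
#' thresholds, input checksums and per-stage record counts, so a rerun with
#' the same configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the result bundle (named list of stage outputs), invisibly
#'   written under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  ind <- config$input_dir
  missing <- .required_inputs[!file.exists(file.path(ind, .required_inputs))]
  if (length(missing))
    stop("missing input file(s): ",
         paste(file.path(ind, missing), collapse = ", "))
  outd <- config$output_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)

  tgt_sizes <- read_chrom_sizes(file.path(ind, "target.chrom.sizes"))
  chains <- parse_chain(file.path(ind, "alignment.chain"))
  genes_src <- read_genes(file.path(ind, "genes_source.tsv"))
  genes_tgt <- read_genes(file.path(ind, "genes_target.tsv"))
  pairs <- read_bedpe(file.path(ind, "interactions.bedpe"),
                      extra_cols = c("id", "replicate", "pet_count"))
  pairs$pet_count <- as.integer(pairs$pet_count)
  k4 <- read_bed(file.path(ind, "peaks_source_H3K4me1.bed"))
  k27_path <- file.path(ind, "peaks_source_H3K27Ac.bed")
  k27 <- if (file.exists(k27_path)) read_bed(k27_path) else k4[0, ]

  # stage 1: source-side preparation ----------------------------------------
  lri <- prepare_interactome(pairs, genes_src, k4, k27,
                             promoter_halfwidth = config$promoter_halfwidth,
                             min_mark_len = config$min_mark_len,
                             min_reciprocal = config$min_reciprocal)
  .write_tsv(lri, file.path(outd, "lri_source.tsv"))

  # stage 2: liftover + synteny ---------------------------------------------
  hms <- map_interactions(lri, chains, min_match = config$min_match)
  ppe <- hms[hms$synteny_class == "P_plus_E", , drop = FALSE]
  red <- flag_redundant(ppe, frac = config$redundancy_frac)
  hms <- merge(hms, red, by = "id", all.x = TRUE, sort = FALSE)
  p_ann <- annotate_region(
    data.frame(chrom = ppe$p_chrom, start = ppe$p_start, end = ppe$p_end),
    genes_tgt, config$promoter_halfwidth)
  e_ann <- annotate_region(
    data.frame(chrom = ppe$e_chrom, start = ppe$e_start, end = ppe$e_end),
    genes_tgt, config$promoter_halfwidth)
  ppe$promoter_category <- p_ann$category
  ppe$connected_gene <- p_ann$gene_ids
  ppe$enhancer_category <- e_ann$category
  ppe$enhancer_intragenic <- e_ann$intragenic
  ppe$spans_multiple_genes <- spans_multiple_genes(ppe, genes_tgt,
                                                   config$promoter_halfwidth)
  hms <- hms[order(match(hms$id, lri$id)), , drop = FALSE]
  .write_tsv(hms, file.path(outd, "hmslri_master.tsv"))
  .write_tsv(ppe, file.path(outd, "hmslri_p_plus_e.tsv"))
  write_bedpe(data.frame(chrom1 = ppe$p_chrom, start1 = ppe$p_start,
                         end1 = ppe$p_end, chrom2 = ppe$e_chrom,
                         start2 = ppe$e_start, end2 = ppe$e_end,
                         id = ppe$id, pet_count = ppe$pet_count),
              file.path(outd, "hmslri_p_plus_e.bedpe"))
  write_washu_longrange(ppe, file.path(outd, "hmslri_longrange.txt"))

  # stage 3: concordance ----------------------------------------------------
  enh <- data.frame(id = ppe$id, chrom = ppe$e_chrom, start = ppe$e_start,
                    end = ppe$e_end)
  layer_files <- list.files(file.path(ind, "peaks_target"),
                            pattern = "\\.bed$", full.names = TRUE)
  peak_layers <- list()
  for (f in layer_files) {
    parts <- strsplit(sub("\\.bed$", "", basename(f)), "__")[[1]]
    peak_layers[[parts[1]]][[parts[2]]] <- read_bed(f)
  }
  conc <- if (length(peak_layers) && nrow(enh))
    mark_concordance(enh, peak_layers, config$min_overlap_bp) else NULL
  cum <- NULL; null_summary <- NULL
  if (!is.null(conc)) {
    .write_tsv(conc$table, file.path(outd, "mark_concordance.tsv"))
    .write_tsv(conc$summary, file.path(outd, "mark_concordance_summary.tsv"))
    matched_sets <- lapply(split(conc$table, conc$table$tissue),
                           function(d) d$id[d$matched])
    cum <- cumulative_match(matched_sets)
    .write_tsv(cum, file.path(outd, "mark_cumulative.tsv"))
    null_enh <- cbind(id = enh$id,
                      shuffle_regions(enh[, c("chrom", "start", "end")],
                                      tgt_sizes, seed = config$seed))
    null_summary <- mark_concordance(null_enh, peak_layers,
                                     config$min_overlap_bp)$summary
    .write_tsv(null_summary, file.path(outd, "mark_concordance_null.tsv"))
  }
  tad_files <- list.files(file.path(ind, "tads"), pattern = "\\.bed$",
                          full.names = TRUE)
  tads <- NULL
  if (length(tad_files) && nrow(ppe)) {
    tad_sets <- lapply(tad_files, read_bed)
    names(tad_sets) <- sub("\\.bed$", "", basename(tad_files))
    tads <- tad_call(ppe, tad_sets)
    .write_tsv(tads$table, file.path(outd, "tad_calls.tsv"))
  }
  loop_files <- list.files(file.path(ind, "loops"), pattern = "\\.bedpe$",
                           full.names = TRUE)
  loops <- NULL
  if (length(loop_files) && nrow(ppe)) {
    loop_sets <- lapply(loop_files, read_bedpe)
    names(loop_sets) <- sub("\\.bedpe$", "", basename(loop_files))
    loops <- loop_representation(ppe, loop_sets,
                                 min_bp = config$loop_overlap_bp)
    .write_tsv(loops$summary, file.path(outd, "loop_representation.tsv"))
  }
  track <- read_bedgraph(file.path(ind, "conservation.bedgraph"))
  cons <- NULL
  if (nrow(enh)) {
    null_regions <- shuffle_regions(enh[, c("chrom", "start", "end")],
                                    tgt_sizes, seed = config$seed + 1L)
    cons <- conservation_compare(enh[, c("chrom", "start", "end")],
                                 null_regions, track)
  }
  ccre_path <- file.path(ind, "ccres.tsv")
  ccre <- NULL
  if (file.exists(ccre_path)) {
    src_enh <- data.frame(id = lri$id, chrom = lri$e_chrom,
                          start = lri$e_start, end = lri$e_end)
    ccre <- ccre_overlap(src_enh, .read_tsv(ccre_path))
    .write_tsv(ccre$per_subclass, file.path(outd, "ccre_subclasses.tsv"))
  }
  vista_path <- file.path(ind, "vista.tsv")
  vista <- if (file.exists(vista_path) && nrow(enh))
    vista_overlap(enh, .read_tsv(vista_path)) else NULL

  # stage 4: disease overlays -----------------------------------------------
  var_path <- file.path(ind, "variants.tsv")
  var_hits <- NULL; motif_calls <- NULL
  if (file.exists(var_path) && nrow(ppe)) {
    variants <- .read_tsv(var_path)
    var_hits <- variants_in_enhancers(variants, ppe,
                                      ppa_min = config$ppa_min, ccres = NULL)
    .write_tsv(var_hits, file.path(outd, "variant_hits.tsv"))
    pwm_path <- file.path(ind, "pwms.txt")
    fa_path <- file.path(ind, "target_genome.fa")
    if (file.exists(pwm_path) && file.exists(fa_path) && nrow(var_hits)) {
      genome <- Biostrings::readDNAStringSet(fa_path)
      names(genome) <- sub(" .*", "", names(genome))
      pwms <- read_pwms(pwm_path)
      vv <- variants[variants$rsid %in% var_hits$rsid, , drop = FALSE]
      motif_calls <- do.call(rbind, lapply(seq_len(nrow(vv)), function(i)
        do.call(rbind, lapply(pwms, function(pw) {
          r <- score_motif_disruption(vv[i, ], genome, pw,
                                      config$effect_threshold)
          data.frame(rsid = r$rsid, motif_id = r$motif_id,
                     best_ref_score = r$best_ref_score,
                     best_alt_score = r$best_alt_score, delta = r$delta,
                     effect = r$effect, stringsAsFactors = FALSE)
        }))))
      .write_tsv(motif_calls, file.path(outd, "motif_disruption.tsv"))
    }
  }
  cnv_path <- file.path(ind, "cnvs.tsv")
  cnv_res <- NULL
  if (file.exists(cnv_path) && nrow(hms)) {
    cnvs <- .read_tsv(cnv_path)
    case <- cnvs[cnvs$cohort == "case", , drop = FALSE]
    ctrl <- cnvs[cnvs$cohort == "control", , drop = FALSE]
    ov <- cnv_overlap(cnvs, ppe)
    eonly <- enhancer_only_disruptions(ov[ov$cohort == "case", , drop = FALSE],
                                       control_cnvs = ctrl)
    enr <- hypergeometric_enrichment(case, ctrl, ppe)
    .write_tsv(ov, file.path(outd, "cnv_overlap.tsv"))
    .write_tsv(eonly, file.path(outd, "cnv_enhancer_only.tsv"))
    cnv_res <- list(overlap = ov, enhancer_only = eonly, enrichment = enr)
  }
  panel_files <- list.files(file.path(ind, "panels"), pattern = "\\.tsv$",
                            full.names = TRUE)
  panels <- NULL
  if (length(panel_files) && nrow(ppe)) {
    panel_tables <- lapply(panel_files, .read_tsv)
    names(panel_tables) <- sub("\\.tsv$", "", basename(panel_files))
    genes <- sort(unique(unlist(strsplit(ppe$connected_gene, ","))))
    genes <- genes[nzchar(genes)]
    panels <- gene_panel_join(genes, panel_tables)
    .write_tsv(panels, file.path(outd, "gene_panels.tsv"))
  }

  # report + manifest ---------------------------------------------------------
  counts <- synteny_class_counts(hms)
  by_state <- synteny_class_counts(hms, by = "enhancer_state")
  report <- list(
    n_input_pairs = nrow(pairs), n_lri = nrow(lri),
    synteny_counts = as.list(counts),
    p_plus_e_pct_active = if ("active" %in% rownames(by_state))
      pct(by_state["active", "P_plus_E"], sum(by_state["active", ])) else NA,
    p_plus_e_pct_poised = if ("poised" %in% rownames(by_state))
      pct(by_state["poised", "P_plus_E"], sum(by_state["poised", ])) else NA,
    conservation_p = if (!is.null(cons)) cons$p_value else NA,
    loop_total_unique_pct = if (!is.null(loops)) loops$total_unique_pct else NA,
    tad_intra_any_pct = if (!is.null(tads)) tads$intra_any_pct else NA,
    ccre_overlap_pct = if (!is.null(ccre)) ccre$overlap_pct else NA,
    cnv_enrichment_p = if (!is.null(cnv_res)) cnv_res$enrichment$p_value else NA)
  manifest <- list(
    seed = config$seed,
    thresholds = config[setdiff(names(config),
                                c("input_dir", "output_dir"))],
    inputs = as.list(tools::md5sum(sort(list.files(ind, recursive = TRUE,
                                                   full.names = TRUE)))),
    stage_counts = list(
      input_pairs = nrow(pairs), lri = nrow(lri),
      synteny = as.list(counts),
      variant_hits = if (is.null(var_hits)) 0L else nrow(var_hits),
      cnv_overlap_rows = if (is.null(cnv_res)) 0L else nrow(cnv_res$overlap)))
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(outd, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(lri = lri, hmslri = hms, p_plus_e = ppe,
                 concordance = conc, cumulative = cum,
                 mark_null = null_summary, tads = tads, loops = loops,
                 conservation = cons, ccre = ccre, vista = vista,
                 variant_hits = var_hits, motif_calls = motif_calls,
                 cnv = cnv_res, panels = panels, report = report,
                 manifest = manifest))
}
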