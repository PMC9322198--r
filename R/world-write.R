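# Serialize a synthetic world to the plain-text input layout the pipeline
# consumes.  Every file that tolerates comments records the generating seed
# in a header line.

#' Write all input files of a synthetic world
#'
#' @param world a `synthetic_world` from [build_world()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("peaks_target", "tads", "loops", "panels"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  seed_line <- sprintf("# seed: %d", world$seed)
  p <- function(...) file.path(dir, ...)

  commented_tsv <- function(df, path) {
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(seed_line, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  commented_bed <- function(df, path) {
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(seed_line, con)
    utils::write.table(.sort_bed(df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  write_chrom_sizes(world$source_chrom_sizes, p("source.chrom.sizes"))
  write_chrom_sizes(world$target_chrom_sizes, p("target.chrom.sizes"))
  write_chain(world$chains, p("alignment.chain"),
              header_comment = sprintf("seed: %d", world$seed))
  commented_tsv(world$genes_source, p("genes_source.tsv"))
  commented_tsv(world$genes_target, p("genes_target.tsv"))

  # raw anchor pairs: alternate left/right orientation so downstream
  # promoter-first normalization is exercised
  it <- world$interactions
  swap <- seq_len(nrow(it)) %% 2L == 0L
  pairs <- data.frame(
    chrom1 = it$chrom, start1 = ifelse(swap, it$e_start, it$p_start),
    end1 = ifelse(swap, it$e_end, it$p_end),
    chrom2 = it$e_chrom, start2 = ifelse(swap, it$p_start, it$e_start),
    end2 = ifelse(swap, it$p_end, it$e_end),
    id = it$id, replicate = it$replicate, pet_count = it$pet_count)
  con <- file(p("interactions.bedpe"), "wt")
  writeLines(seed_line, con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)

  commented_bed(world$peaks_source[world$peaks_source$mark == "H3K4me1",
                                   c("chrom", "start", "end", "mark")],
                p("peaks_source_H3K4me1.bed"))
  commented_bed(world$peaks_source[world$peaks_source$mark == "H3K27Ac",
                                   c("chrom", "start", "end", "mark")],
                p("peaks_source_H3K27Ac.bed"))
  for (tissue in names(world$peak_layers)) {
    layer <- world$peak_layers[[tissue]]
    for (mark in names(layer))
      commented_bed(cbind(layer[[mark]], mark),
                    p("peaks_target", sprintf("%s__%s.bed", tissue, mark)))
  }
  for (ds in names(world$tad_sets))
    commented_bed(world$tad_sets[[ds]], p("tads", paste0(ds, ".bed")))
  for (ds in names(world$loop_sets)) {
    con <- file(p("loops", paste0(ds, ".bedpe")), "wt")
    writeLines(seed_line, con)
    utils::write.table(world$loop_sets[[ds]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  commented_bed(world$conservation, p("conservation.bedgraph"))
  if (!is.null(world$variants))
    commented_tsv(world$variants[, c("chrom", "pos", "rsid", "ref", "alt",
                                     "trait", "ppa")], p("variants.tsv"))
  cnvs <- rbind(world$cnv_case, world$cnv_control)
  commented_tsv(cnvs[, c("chrom", "start", "end", "cnv_type", "cohort",
                         "phenotype", "subject_id", "pathogenicity_class")],
                p("cnvs.tsv"))
  if (length(world$pwms)) write_pwms(world$pwms, p("pwms.txt"))
  if (!is.null(world$ccres)) commented_tsv(world$ccres, p("ccres.tsv"))
  if (!is.null(world$vista)) commented_tsv(world$vista, p("vista.tsv"))
  for (panel in names(world$gene_panels))
    commented_tsv(world$gene_panels[[panel]],
                  p("panels", paste0(panel, ".tsv")))
  seqs <- Biostrings::DNAStringSet(unlist(world$target_seq))
  Biostrings::writeXStringSet(seqs, p("target_genome.fa"))
  invisible(dir)
}
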