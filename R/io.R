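# Plain-text readers and writers for the formats the pipeline exchanges.
# All coordinates on disk are 0-based half-open (BED convention); TSV tables
# carry a header row, BED-family files do not.  Writers emit deterministic,
# sorted output so that reruns are byte-identical.

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, quote = "", ...)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.sort_bed <- function(df) df[order(df$chrom, df$start, df$end), , drop = FALSE]

#' Read a BED3/4/6 file
#'
#' @param path input path; `#` and `track` lines are skipped.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  parts <- strsplit(lines, "\t")
  nf <- min(lengths(parts))
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(nf, 6L))]
  df <- as.data.frame(do.call(rbind, lapply(parts, `[`, seq_along(cols))),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("invalid BED interval in ", path)
  df
}

#' Write a BED file (sorted, 0-based half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional further
#'   BED columns (written in order).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  df <- .sort_bed(df)
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file with optional extra columns
#'
#' @param path input path.
#' @param extra_cols names for columns beyond the first six.
#' @return data.frame with `chrom1/start1/end1/chrom2/start2/end2` plus any
#'   extra columns.
#' @export
read_bedpe <- function(path, extra_cols = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  base_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!length(lines)) {
    df <- as.data.frame(setNames(rep(list(character(0)), 6), base_cols))
    return(df)
  }
  parts <- strsplit(lines, "\t")
  cols <- c(base_cols, extra_cols)
  df <- as.data.frame(do.call(rbind, lapply(parts, `[`, seq_along(cols))),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  for (cc in c("start1", "end1", "start2", "end2"))
    df[[cc]] <- as.integer(df[[cc]])
  df
}

#' Write a BEDPE file
#'
#' @param df data.frame whose first six columns are the two anchors; any
#'   further columns are appended.
#' @param path output path.
#' @export
write_bedpe <- function(df, path) {
  df <- df[order(df$chrom1, df$start1, df$chrom2, df$start2), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path input path.
#' @return data.frame `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path)
  names(df)[4] <- "score"
  df$score <- as.numeric(df$score)
  df
}

#' Write a bedGraph track
#' @param df data.frame `chrom`, `start`, `end`, `score`.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  write_bed(df[, c("chrom", "start", "end", "score")], path)
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with name and length columns (no header).
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Write chromosome sizes
#' @param sizes named integer vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Read gene models from the pipeline's TSV layout
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss` (0-based position), `start`,
#' `end` (0-based half-open gene body).
#' @param path input path.
#' @return data.frame of gene models.
#' @export
read_genes <- function(path) .read_tsv(path)

#' Write gene models
#' @param genes gene-model data.frame (see [read_genes()]).
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  .write_tsv(genes[order(genes$chrom, genes$start), ], path)
}

#' Read position probability matrices from simple matrix text
#'
#' Format: records introduced by `>motif_id<TAB>tf_name`, followed by one
#' row per motif position with four whitespace-separated probabilities
#' (A C G T).
#' @param path input path.
#' @return list of PWM objects (`motif_id`, `tf_name`, `matrix`).
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  hdr <- grep("^>", lines)
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    meta <- strsplit(sub("^>", "", lines[hdr[i]]), "\t")[[1]]
    rows <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "[ \t]+"),
                                 as.numeric))
    colnames(mat) <- c("A", "C", "G", "T")
    out[[i]] <- pwm_motif(meta[1], if (length(meta) > 1) meta[2] else meta[1],
                          mat)
  }
  out
}

#' Write position probability matrices
#' @param pwms list of PWM objects.
#' @param path output path.
#' @export
write_pwms <- function(pwms, path) {
  out <- character(0)
  for (p in pwms) {
    out <- c(out, sprintf(">%s\t%s", p$motif_id, p$tf_name),
             apply(p$matrix, 1, function(r) paste(format(r, trim = TRUE),
                                                  collapse = "\t")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write interactions as BEDPE with id/replicate/PET-count columns
#'
#' @param interactions interaction table with promoter (`chrom`, `p_start`,
#'   `p_end`) and enhancer (`e_chrom`, `e_start`, `e_end`) anchors plus
#'   `id`, `replicate`, `pet_count`.
#' @param path output path.
#' @export
write_interactions_bedpe <- function(interactions, path) {
  df <- data.frame(chrom1 = interactions$chrom, start1 = interactions$p_start,
                   end1 = interactions$p_end, chrom2 = interactions$e_chrom,
                   start2 = interactions$e_start, end2 = interactions$e_end,
                   id = interactions$id, replicate = interactions$replicate,
                   pet_count = interactions$pet_count)
  write_bedpe(df, path)
}

#' Read interactions written by [write_interactions_bedpe()]
#' @param path input path.
#' @return interaction anchor table.
#' @export
read_interactions_bedpe <- function(path) {
  df <- read_bedpe(path, extra_cols = c("id", "replicate", "pet_count"))
  data.frame(id = df$id, replicate = df$replicate,
             pet_count = as.integer(df$pet_count),
             chrom = df$chrom1, p_start = df$start1, p_end = df$end1,
             e_chrom = df$chrom2, e_start = df$start2, e_end = df$end2,
             stringsAsFactors = FALSE)
}

#' Write a WashU-browser longrange text track
#'
#' One line per record:
#' `chrom<TAB>start<TAB>end<TAB>chrom2:start2-end2,score`, sorted by
#' coordinate; the PET count is used as the loop score.
#'
#' @param hmslris remapped-interaction table restricted to records with both
#'   anchors present on one chromosome; must carry `p_chrom`, `p_start`,
#'   `p_end`, `e_chrom`, `e_start`, `e_end`, `pet_count`.
#' @param path output path.
#' @export
write_washu_longrange <- function(hmslris, path) {
  if (nrow(hmslris) == 0) { writeLines(character(0), path); return(invisible(path)) }
  df <- data.frame(chrom = hmslris$p_chrom, start = hmslris$p_start,
                   end = hmslris$p_end,
                   partner = sprintf("%s:%d-%d,%d", hmslris$e_chrom,
                                     hmslris$e_start, hmslris$e_end,
                                     hmslris$pet_count))
  df <- df[order(df$chrom, df$start, df$end), ]
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                     df$partner), path)
  invisible(path)
}

#' Read a WashU longrange track back into anchor pairs
#' @param path input path.
#' @return data.frame with both anchors and the score.
#' @export
read_washu_longrange <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(p_chrom = character(0), p_start = integer(0),
                      p_end = integer(0), e_chrom = character(0),
                      e_start = integer(0), e_end = integer(0),
                      score = integer(0)))
  parts <- do.call(rbind, strsplit(lines, "\t"))
  m <- regmatches(parts[, 4],
                  regexec("^([^:]+):([0-9]+)-([0-9]+),([0-9]+)$", parts[, 4]))
  data.frame(
    p_chrom = parts[, 1], p_start = as.integer(parts[, 2]),
    p_end = as.integer(parts[, 3]),
    e_chrom = vapply(m, `[`, character(1), 2),
    e_start = as.integer(vapply(m, `[`, character(1), 3)),
    e_end = as.integer(vapply(m, `[`, character(1), 4)),
    score = as.integer(vapply(m, `[`, character(1), 5)),
    stringsAsFactors = FALSE
  )
}
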