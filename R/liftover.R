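# Chain-based interval remapping with a minimum mapped-base fraction
# (the classic liftOver "minMatch" contract).
#
# One interval maps through at most one chain: among the chains whose source
# span overlaps the interval, the highest-scoring one is used (ties broken by
# the lower chain id), mirroring default single-mapping liftOver behaviour.
# The mapped fraction is the share of interval bases that fall inside the
# chain's aligned blocks; at fraction >= min_match the result is the
# enclosing span of the mapped bases in target coordinates, reported as a
# forward-strand interval even for reverse-strand chains.

#' Map one interval through a chain set
#'
#' @param chrom,start,end the query interval (0-based half-open).
#' @param chains list of `chain_alignment` objects (see [parse_chain()]).
#' @param min_match minimum fraction of interval bases that must fall in
#'   aligned blocks for the mapping to succeed (default 0.5, i.e. more than
#'   half the bases lift over; the comparison is `>=`).
#' @return a list with `status` ("mapped"/"unmapped"), `reason` (for
#'   unmapped: "no_chain" or "below_min_match"), `t_chrom`, `t_start`,
#'   `t_end` (0-based half-open, forward strand; NA when unmapped),
#'   `mapped_fraction`, and `chain_id`.
#' @export
map_interval <- function(chrom, start, end, chains, min_match = 0.5) {
  stopifnot(end > start)
  unmapped <- function(reason, frac = 0, id = NA_integer_) {
    list(status = "unmapped", reason = reason,
         t_chrom = NA_character_, t_start = NA_integer_, t_end = NA_integer_,
         mapped_fraction = frac, chain_id = id)
  }
  cand <- Filter(function(ch)
    ch$s_chrom == chrom && ch$s_start < end && ch$s_end > start, chains)
  if (!length(cand)) return(unmapped("no_chain"))
  scores <- vapply(cand, `[[`, numeric(1), "score")
  ids <- vapply(cand, `[[`, integer(1), "id")
  best <- order(-scores, ids)[1]
  ch <- cand[[best]]
  bl <- chain_blocks(ch)
  ov_s <- pmax(start, bl$s_start)
  ov_e <- pmin(end, bl$s_end)
  hit <- ov_e > ov_s
  mapped_bases <- sum(pmax(0L, ov_e - ov_s))
  frac <- mapped_bases / (end - start)
  if (frac < min_match) return(unmapped("below_min_match", frac, ch$id))
  i1 <- which(hit)[1]
  i2 <- which(hit)[sum(hit)]
  # first and last mapped base, translated block-locally into target
  # coordinates (alignment space)
  q1 <- bl$t_start[i1] + (ov_s[i1] - bl$s_start[i1])
  q2 <- bl$t_start[i2] + (ov_e[i2] - bl$s_start[i2])
  if (ch$t_strand == "-") {
    fwd <- reflect_interval(q1, q2, ch$t_size)
    q1 <- fwd[1]; q2 <- fwd[2]
  }
  list(status = "mapped", reason = NA_character_,
       t_chrom = ch$t_chrom, t_start = as.integer(q1), t_end = as.integer(q2),
       mapped_fraction = frac, chain_id = ch$id)
}

#' Map a table of intervals through a chain set
#'
#' Vectorized wrapper around [map_interval()].
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open);
#'   extra columns are carried through.
#' @inheritParams map_interval
#' @return `df` with appended columns `status`, `reason`, `t_chrom`,
#'   `t_start`, `t_end`, `mapped_fraction`, `chain_id`.
#' @export
liftover_intervals <- function(df, chains, min_match = 0.5) {
  res <- lapply(seq_len(nrow(df)), function(i)
    map_interval(df$chrom[i], df$start[i], df$end[i], chains, min_match))
  out <- data.frame(
    status = vapply(res, `[[`, character(1), "status"),
    reason = vapply(res, `[[`, character(1), "reason"),
    t_chrom = vapply(res, `[[`, character(1), "t_chrom"),
    t_start = vapply(res, `[[`, integer(1), "t_start"),
    t_end = vapply(res, `[[`, integer(1), "t_end"),
    mapped_fraction = vapply(res, `[[`, numeric(1), "mapped_fraction"),
    chain_id = vapply(res, `[[`, integer(1), "chain_id"),
    stringsAsFactors = FALSE
  )
  cbind(df, out)
}

#' Liftover a BED file, writing mapped and rejected outputs
#'
#' Mirrors the two-output contract of the classic command-line tool: mapped
#' intervals go to `out_path` as BED, rejects to `unmapped_path` with the
#' failure reason in the name column.
#'
#' @param bed_path input BED3+ file.
#' @param chain_path UCSC chain file.
#' @param out_path output BED for mapped intervals.
#' @param unmapped_path output BED for rejected intervals.
#' @inheritParams map_interval
#' @return the mapping table from [liftover_intervals()], invisibly.
#' @export
liftover_bed <- function(bed_path, chain_path, out_path, unmapped_path,
                         min_match = 0.5) {
  df <- read_bed(bed_path)
  chains <- parse_chain(chain_path)
  res <- liftover_intervals(df, chains, min_match)
  ok <- res$status == "mapped"
  mapped <- data.frame(chrom = res$t_chrom[ok], start = res$t_start[ok],
                       end = res$t_end[ok],
                       name = if ("name" %in% names(df)) df$name[ok]
                              else as.character(which(ok)))
  write_bed(mapped[order(mapped$chrom, mapped$start), ], out_path)
  rej <- data.frame(chrom = res$chrom[!ok], start = res$start[!ok],
                    end = res$end[!ok], name = res$reason[!ok])
  write_bed(rej, unmapped_path)
  invisible(res)
}
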