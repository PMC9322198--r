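# UCSC chain format support.
#
# A chain describes one scored pairwise alignment as an ordered run of
# ungapped blocks separated by gaps on the source (dt) and/or target (dq)
# side.  Header layout (all coordinates 0-based half-open):
#
#   chain score sName sSize sStrand sStart sEnd tName tSize tStrand tStart tEnd id
#   size dt dq
#   ...
#   size
#
# The first sequence named in the header is the genome intervals are lifted
# FROM (the "t" fields of UCSC's own documentation); the second is the genome
# they are lifted TO.  When the target strand is "-", target coordinates are
# counted from the end of the target chromosome, per UCSC convention.

#' Construct a chain alignment
#'
#' @param id integer chain id.
#' @param score alignment score (here: total aligned bases, by the
#'   generator's convention).
#' @param s_chrom,s_size,s_start,s_end source sequence name, length and
#'   0-based half-open aligned span; the source strand is always `+`.
#' @param t_chrom,t_size,t_strand,t_start,t_end target side; when
#'   `t_strand == "-"`, `t_start`/`t_end` are reverse-strand coordinates
#'   (counted from the chromosome end).
#' @param size integer vector of ungapped block sizes (all >= 1).
#' @param dt,dq integer vectors (length `length(size) - 1`) of source/target
#'   gap sizes between consecutive blocks.
#' @return an object of class `chain_alignment`.
#' @export
chain_alignment <- function(id, score, s_chrom, s_size, s_start, s_end,
                            t_chrom, t_size, t_strand, t_start, t_end,
                            size, dt = integer(0), dq = integer(0)) {
  ch <- structure(
    list(id = as.integer(id), score = as.numeric(score),
         s_chrom = s_chrom, s_size = as.integer(s_size),
         s_start = as.integer(s_start), s_end = as.integer(s_end),
         t_chrom = t_chrom, t_size = as.integer(t_size),
         t_strand = t_strand, t_start = as.integer(t_start),
         t_end = as.integer(t_end),
         size = as.integer(size), dt = as.integer(dt), dq = as.integer(dq)),
    class = "chain_alignment"
  )
  validate_chain(ch)
  ch
}

#' Validate chain block arithmetic
#'
#' Checks that block sizes plus gaps reproduce the header spans and that all
#' sizes are admissible.
#' @param ch a `chain_alignment`.
#' @return `ch`, invisibly; errors on violation naming the chain id.
#' @export
validate_chain <- function(ch) {
  n <- length(ch$size)
  if (n < 1L || any(ch$size < 1L))
    stop(sprintf("chain %d: block sizes must be >= 1", ch$id))
  if (length(ch$dt) != n - 1L || length(ch$dq) != n - 1L)
    stop(sprintf("chain %d: expected %d gap entries, got %d/%d",
                 ch$id, n - 1L, length(ch$dt), length(ch$dq)))
  if (any(ch$dt < 0L) || any(ch$dq < 0L))
    stop(sprintf("chain %d: negative gap", ch$id))
  s_span <- sum(ch$size) + sum(ch$dt)
  t_span <- sum(ch$size) + sum(ch$dq)
  if (s_span != ch$s_end - ch$s_start)
    stop(sprintf(
      "chain %d: source block arithmetic mismatch (blocks+gaps = %d, header span = %d)",
      ch$id, s_span, ch$s_end - ch$s_start))
  if (t_span != ch$t_end - ch$t_start)
    stop(sprintf(
      "chain %d: target block arithmetic mismatch (blocks+gaps = %d, header span = %d)",
      ch$id, t_span, ch$t_end - ch$t_start))
  if (ch$s_end > ch$s_size || ch$t_end > ch$t_size || ch$s_start < 0L || ch$t_start < 0L)
    stop(sprintf("chain %d: span outside chromosome bounds", ch$id))
  invisible(ch)
}

# per-block coordinates in "alignment space": source forward coordinates and
# target coordinates as written in the chain (reverse-strand when t_strand
# is "-").  Returns a data.frame with s_start/s_end/t_start/t_end per block.
chain_blocks <- function(ch) {
  n <- length(ch$size)
  s_starts <- ch$s_start + c(0L, cumsum(ch$size[-n] + ch$dt))
  t_starts <- ch$t_start + c(0L, cumsum(ch$size[-n] + ch$dq))
  data.frame(
    s_start = s_starts, s_end = s_starts + ch$size,
    t_start = t_starts, t_end = t_starts + ch$size
  )
}

# reverse-strand target coordinate p (alignment space, half-open interval
# [s,e)) to forward-strand interval
reflect_interval <- function(start, end, size) {
  c(size - end, size - start)
}

#' Parse a UCSC chain file
#'
#' @param path path to a chain file (plain text; `#` comment lines allowed).
#' @return list of `chain_alignment` objects; malformed records (block
#'   arithmetic that does not reproduce the header spans) raise an error
#'   naming the chain id and the failing sum.
#' @export
parse_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- trimws(lines)
  hdr_idx <- grep("^chain\\b", lines)
  if (!length(hdr_idx)) stop("no chain records found in ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  chains <- vector("list", length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    hdr <- strsplit(lines[hdr_idx[i]], "[ \t]+")[[1]]
    if (length(hdr) != 13L)
      stop("malformed chain header: ", lines[hdr_idx[i]])
    body <- lines[(hdr_idx[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    if (!length(body)) stop("chain ", hdr[13], ": no alignment blocks")
    parts <- strsplit(body, "[ \t]+")
    nf <- lengths(parts)
    if (any(nf[-length(nf)] != 3L) || nf[length(nf)] != 1L)
      stop("chain ", hdr[13], ": malformed block lines")
    mat <- matrix(0L, nrow = length(parts), ncol = 3)
    for (j in seq_along(parts)) mat[j, seq_len(nf[j])] <- as.integer(parts[[j]])
    if (hdr[5] != "+")
      stop("chain ", hdr[13], ": source strand must be '+'")
    chains[[i]] <- chain_alignment(
      id = as.integer(hdr[13]), score = as.numeric(hdr[2]),
      s_chrom = hdr[3], s_size = as.integer(hdr[4]),
      s_start = as.integer(hdr[6]), s_end = as.integer(hdr[7]),
      t_chrom = hdr[8], t_size = as.integer(hdr[9]), t_strand = hdr[10],
      t_start = as.integer(hdr[11]), t_end = as.integer(hdr[12]),
      size = mat[, 1],
      dt = mat[-nrow(mat), 2], dq = mat[-nrow(mat), 3]
    )
  }
  chains
}

#' Write chain alignments in UCSC chain format
#'
#' @param chains list of `chain_alignment` objects.
#' @param path output path.
#' @param header_comment optional comment line(s) written at the top
#'   (prefixed with `#`).
#' @export
write_chain <- function(chains, path, header_comment = NULL) {
  out <- character(0)
  if (!is.null(header_comment)) out <- paste0("# ", header_comment)
  for (ch in chains) {
    validate_chain(ch)
    out <- c(out, sprintf(
      "chain %s %s %d + %d %d %s %d %s %d %d %d",
      format(ch$score, scientific = FALSE), ch$s_chrom, ch$s_size,
      ch$s_start, ch$s_end, ch$t_chrom, ch$t_size, ch$t_strand,
      ch$t_start, ch$t_end, ch$id))
    n <- length(ch$size)
    if (n > 1L)
      out <- c(out, sprintf("%d\t%d\t%d", ch$size[-n], ch$dt, ch$dq))
    out <- c(out, as.character(ch$size[n]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Invert a chain alignment
#'
#' Swaps source and target so that intervals can be mapped back.  When the
#' original target strand is `-`, the source coordinates of the inverse are
#' flipped to the forward strand (the chain convention requires a `+` source
#' strand) and the block order is reversed.
#'
#' @param ch a `chain_alignment`.
#' @return the inverse `chain_alignment`.
#' @export
invert_chain <- function(ch) {
  if (ch$t_strand == "+") {
    chain_alignment(
      id = ch$id, score = ch$score,
      s_chrom = ch$t_chrom, s_size = ch$t_size,
      s_start = ch$t_start, s_end = ch$t_end,
      t_chrom = ch$s_chrom, t_size = ch$s_size, t_strand = "+",
      t_start = ch$s_start, t_end = ch$s_end,
      size = ch$size, dt = ch$dq, dq = ch$dt
    )
  } else {
    # forward-strand target span of the original chain
    fwd <- reflect_interval(ch$t_start, ch$t_end, ch$t_size)
    n <- length(ch$size)
    chain_alignment(
      id = ch$id, score = ch$score,
      s_chrom = ch$t_chrom, s_size = ch$t_size,
      s_start = fwd[1], s_end = fwd[2],
      # the original source read against a '-' target becomes a '-' target
      # itself, in reverse-strand coordinates counted from the source end
      t_chrom = ch$s_chrom, t_size = ch$s_size, t_strand = "-",
      t_start = ch$s_size - ch$s_end, t_end = ch$s_size - ch$s_start,
      size = rev(ch$size), dt = rev(ch$dq), dq = rev(ch$dt)
    )
  }
}
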