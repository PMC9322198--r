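# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-implementations (per-base loops, exhaustive window
# enumeration) kept separate from the package's algorithms.

# Per-base brute-force liftover: maps every base of the interval
# individually through the chain blocks and summarizes.
oracle_map_interval <- function(chrom, start, end, chains, min_match = 0.5) {
  cand <- Filter(function(ch)
    ch$s_chrom == chrom && ch$s_start < end && ch$s_end > start, chains)
  if (!length(cand))
    return(list(status = "unmapped", reason = "no_chain",
                mapped_fraction = 0))
  scores <- vapply(cand, function(ch) ch$score, numeric(1))
  ids <- vapply(cand, function(ch) ch$id, integer(1))
  ch <- cand[[order(-scores, ids)[1]]]
  # map every base of the query individually through the blocks
  bases <- start:(end - 1L)
  fwd_pos <- rep(NA_integer_, length(bases))
  s_pos <- ch$s_start; t_pos <- ch$t_start
  n <- length(ch$size)
  for (i in seq_len(n)) {
    sel <- bases >= s_pos & bases < s_pos + ch$size[i]
    if (any(sel)) {
      tb <- t_pos + (bases[sel] - s_pos)
      fwd_pos[sel] <- if (ch$t_strand == "-") ch$t_size - tb - 1L else tb
    }
    if (i < n) {
      s_pos <- s_pos + ch$size[i] + ch$dt[i]
      t_pos <- t_pos + ch$size[i] + ch$dq[i]
    }
  }
  frac <- mean(!is.na(fwd_pos))
  if (frac < min_match)
    return(list(status = "unmapped", reason = "below_min_match",
                mapped_fraction = frac, chain_id = ch$id))
  mapped <- fwd_pos[!is.na(fwd_pos)]
  list(status = "mapped", t_chrom = ch$t_chrom,
       t_start = min(mapped), t_end = max(mapped) + 1L,
       mapped_fraction = frac, chain_id = ch$id)
}

# Random but arithmetically valid chain battery over a small genome.
random_chains <- function(n_chains, seed) {
  set.seed(seed)
  chains <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    nb <- sample(1:6, 1)
    size <- sample(20:400, nb, replace = TRUE)
    dt <- if (nb > 1) sample(0:150, nb - 1, replace = TRUE) else integer(0)
    dq <- if (nb > 1) sample(0:150, nb - 1, replace = TRUE) else integer(0)
    # avoid zero-length gap lines (dt = dq = 0 would merge blocks)
    fix <- which(dt + dq == 0)
    if (length(fix)) dt[fix] <- 1L
    s_span <- sum(size) + sum(dt)
    t_span <- sum(size) + sum(dq)
    s_start <- sample(0:2000, 1)
    t_start <- sample(0:2000, 1)
    chains[[i]] <- chain_alignment(
      id = i, score = sample(1000:100000, 1),
      s_chrom = paste0("src", sample(1:3, 1)),
      s_size = s_start + s_span + sample(100:1000, 1),
      s_start = s_start, s_end = s_start + s_span,
      t_chrom = paste0("tgt", sample(1:3, 1)),
      t_size = t_start + t_span + sample(100:1000, 1),
      t_strand = sample(c("+", "-"), 1),
      t_start = t_start, t_end = t_start + t_span,
      size = size, dt = dt, dq = dq)
  }
  chains
}

# Exhaustive window x strand PWM scorer operating on plain strings.
REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_motif_best <- function(seq_str, pos, allele, mat, pseudocount = 0.01) {
  L <- nrow(mat)
  seq_chars <- strsplit(seq_str, "")[[1]]
  seq_chars[pos] <- allele
  best <- -Inf
  for (s in max(1, pos - L + 1):min(pos, length(seq_chars) - L + 1)) {
    win <- seq_chars[s:(s + L - 1)]
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rev(unname(REVCOMP[win]))
      sc <- 0
      for (k in seq_len(L))
        sc <- sc + log2((unname(mat[k, w[k]]) + pseudocount) / 0.25)
      if (sc > best) best <- sc
    }
  }
  best
}

# small convenience: a default world cached per test file run
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_world(world_config())
    cache
  }
})
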