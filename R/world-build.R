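# Synthetic paired-genome generator.
#
# A source genome is partitioned into 50 kb interaction slots; the target
# genome is produced from it by a recorded script of block copies,
# inversions, inter-chromosome translocations and deletions, and the
# emitted chain file exactly describes that mapping.  Interactions are
# planted one per slot so that every synteny class has known membership:
#
#   P_plus_E - slot fully preserved on one target chromosome
#              (half the slots via a forward chain, half via an inverted
#              chain, so reverse-strand liftover is always exercised)
#   split    - promoter half and enhancer half translocated to two
#              different target chromosomes
#   E_only   - the promoter anchor is 60% deleted (retained fraction below
#              the 0.5 minMatch), realized as a chain gap
#   P_only   - same, for the enhancer anchor
#   lost     - both anchors fall entirely inside deleted blocks
#
# All annotation layers (genes, peaks, TADs, loops, conservation, variants,
# CNV cohorts, PWMs, cCREs, validated enhancers, gene panels) are planted
# with recorded truth so downstream stages are testable without downloads.

# ---- chain construction helpers -------------------------------------------

# Build one chain for a source chromosome copied colinearly to a target
# chromosome, with deletion windows realized as source gaps (dt) and
# insertion points realized as target gaps (dq).
.build_linear_chain <- function(id, s_chrom, s_len, t_chrom, t_strand,
                                deletions, insertions, t_margin = 3000L) {
  bp <- sort(unique(c(0L, s_len, deletions$start, deletions$end,
                      insertions$pos)))
  seg <- data.frame(start = bp[-length(bp)], end = bp[-1])
  in_del <- rep(FALSE, nrow(seg))
  if (nrow(deletions))
    for (i in seq_len(nrow(deletions)))
      in_del <- in_del | (seg$start >= deletions$start[i] &
                            seg$end <= deletions$end[i])
  blocks <- seg[!in_del, , drop = FALSE]
  nb <- nrow(blocks)
  size <- blocks$end - blocks$start
  dt <- integer(0); dq <- integer(0)
  if (nb > 1L) {
    dt <- blocks$start[-1] - blocks$end[-nb]
    dq <- vapply(seq_len(nb - 1L), function(i)
      sum(insertions$len[insertions$pos >= blocks$end[i] &
                           insertions$pos <= blocks$start[i + 1L]]),
      numeric(1))
    dq <- as.integer(dq)
  }
  t_starts <- t_margin + c(0L, cumsum(size[-nb] + dq))
  t_end <- t_margin + sum(size) + sum(dq)
  t_size <- t_end + t_margin
  ch <- chain_alignment(
    id = id, score = sum(size),
    s_chrom = s_chrom, s_size = s_len, s_start = blocks$start[1],
    s_end = blocks$end[nb],
    t_chrom = t_chrom, t_size = t_size, t_strand = t_strand,
    t_start = t_margin, t_end = t_end,
    size = size, dt = dt, dq = dq)
  list(chain = ch,
       blocks = data.frame(s_chrom = s_chrom, s_start = blocks$start,
                           s_end = blocks$end, t_chrom = t_chrom,
                           t_strand = t_strand, t_size = t_size,
                           t_start = t_starts, stringsAsFactors = FALSE))
}

# Truth mapping of an interval fully contained in one recorded block;
# returns c(start, end) forward-strand target coordinates, or NULL.
.truth_map <- function(blocks, chrom, a, b) {
  hit <- which(blocks$s_chrom == chrom & blocks$s_start <= a &
                 blocks$s_end >= b)
  if (!length(hit)) return(NULL)
  i <- hit[1]
  q1 <- blocks$t_start[i] + (a - blocks$s_start[i])
  q2 <- blocks$t_start[i] + (b - blocks$s_start[i])
  if (blocks$t_strand[i] == "-") {
    fwd <- reflect_interval(q1, q2, blocks$t_size[i])
    q1 <- fwd[1]; q2 <- fwd[2]
  }
  list(chrom = blocks$t_chrom[i], start = as.integer(q1),
       end = as.integer(q2))
}

.rand_dna <- function(len) {
  rawToChar(sample(charToRaw("ACGT"), len, replace = TRUE))
}

# ---- main generator --------------------------------------------------------

#' Build a synthetic paired-genome world with planted truth
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_world`: chromosome sizes for both
#'   genomes, the chain set, gene models, the planted interaction table
#'   (with `truth_class` and expected target coordinates), peak layers,
#'   TAD/loop sets, a conservation track, risk variants, CNV cohorts with
#'   the realized 2x2 table, PWMs with planted disruption truth, cCRE and
#'   validated-enhancer sets, gene panels, the target genome sequence, and
#'   the seed.
#' @export
build_world <- function(config = world_config()) {
  cfg <- validate_world_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_per_class
  al <- cfg$anchor_len
  keep <- as.integer(round(cfg$partial_keep_frac * al))
  n1 <- n[["P_plus_E"]]
  n1a <- ceiling(n1 / 2); n1b <- n1 - n1a

  # slot table: one interaction per slot
  slots <- rbind(
    if (n1a) data.frame(class = "P_plus_E", chrom = "mchr1", k = seq_len(n1a)),
    if (n[["E_only"]]) data.frame(class = "E_only", chrom = "mchr1",
                                  k = n1a + seq_len(n[["E_only"]])),
    if (n[["P_only"]]) data.frame(class = "P_only", chrom = "mchr1",
                                  k = n1a + n[["E_only"]] + seq_len(n[["P_only"]])),
    if (n[["lost"]]) data.frame(class = "lost", chrom = "mchr1",
                                k = n1a + n[["E_only"]] + n[["P_only"]] +
                                  seq_len(n[["lost"]])),
    if (n[["split"]]) data.frame(class = "split", chrom = "mchr2",
                                 k = seq_len(n[["split"]])),
    if (n1b) data.frame(class = "P_plus_E", chrom = "mchr3", k = seq_len(n1b))
  )
  if (is.null(slots) || nrow(slots) == 0)
    stop("infeasible configuration: no interactions requested")
  slots$offset <- cfg$margin + (slots$k - 1L) * cfg$slot_len
  nslot <- c(mchr1 = sum(slots$chrom == "mchr1"),
             mchr2 = sum(slots$chrom == "mchr2"),
             mchr3 = sum(slots$chrom == "mchr3"))
  src_sizes <- 2L * cfg$margin + nslot * cfg$slot_len
  names(src_sizes) <- names(nslot)
  src_sizes <- src_sizes[nslot > 0]

  # deletion windows (absolute source coordinates), per class
  dels <- list(mchr1 = data.frame(start = integer(0), end = integer(0)))
  for (i in which(slots$chrom == "mchr1")) {
    off <- slots$offset[i]
    d <- switch(slots$class[i],
      E_only = data.frame(start = off + cfg$p_off + keep,
                          end = off + cfg$p_off + al + 1000L),
      P_only = data.frame(start = off + cfg$e_off + keep,
                          end = off + cfg$e_off + al + 1000L),
      lost = data.frame(start = off + c(cfg$p_off, cfg$e_off) - 500L,
                        end = off + c(cfg$p_off, cfg$e_off) + al + 500L),
      NULL)
    if (!is.null(d)) dels$mchr1 <- rbind(dels$mchr1, d)
  }

  chains <- list(); blocks <- list(); next_id <- 1L
  for (cn in c("mchr1", "mchr3")) {
    if (!cn %in% names(src_sizes)) next
    ins_pos <- cfg$margin + seq_len(max(0L, nslot[[cn]] - 1L)) * cfg$slot_len
    res <- .build_linear_chain(
      id = next_id, s_chrom = cn, s_len = unname(src_sizes[cn]),
      t_chrom = if (cn == "mchr1") "hchr1" else "hchr4",
      t_strand = if (cn == "mchr1") "+" else "-",
      deletions = if (cn == "mchr1") dels$mchr1
                  else data.frame(start = integer(0), end = integer(0)),
      insertions = data.frame(pos = ins_pos,
                              len = rep(cfg$insert_len, length(ins_pos))))
    chains[[length(chains) + 1L]] <- res$chain
    blocks[[length(blocks) + 1L]] <- res$blocks
    next_id <- next_id + 1L
  }
  # split slots: promoter half -> hchr2, enhancer half -> hchr3
  if ("mchr2" %in% names(src_sizes)) {
    half <- 20000L
    for (j in seq_len(nslot[["mchr2"]])) {
      off <- cfg$margin + (j - 1L) * cfg$slot_len
      for (part in 1:2) {
        s0 <- if (part == 1) off else off + half
        s1 <- if (part == 1) off + half else off + cfg$slot_len
        tch <- if (part == 1) "hchr2" else "hchr3"
        pitch <- (s1 - s0) + 2000L
        t0 <- 3000L + (j - 1L) * pitch
        t_size <- 6000L + nslot[["mchr2"]] * pitch
        chains[[length(chains) + 1L]] <- chain_alignment(
          id = next_id, score = s1 - s0,
          s_chrom = "mchr2", s_size = unname(src_sizes["mchr2"]),
          s_start = s0, s_end = s1,
          t_chrom = tch, t_size = t_size, t_strand = "+",
          t_start = t0, t_end = t0 + (s1 - s0), size = s1 - s0)
        blocks[[length(blocks) + 1L]] <- data.frame(
          s_chrom = "mchr2", s_start = s0, s_end = s1, t_chrom = tch,
          t_strand = "+", t_size = t_size, t_start = t0,
          stringsAsFactors = FALSE)
        next_id <- next_id + 1L
      }
    }
  }
  if (cfg$identity_chrom) {
    src_sizes <- c(src_sizes, mchrI = 100000L)
    chains[[length(chains) + 1L]] <- chain_alignment(
      id = next_id, score = 100000L, s_chrom = "mchrI", s_size = 100000L,
      s_start = 0L, s_end = 100000L, t_chrom = "hchrI", t_size = 100000L,
      t_strand = "+", t_start = 0L, t_end = 100000L, size = 100000L)
    blocks[[length(blocks) + 1L]] <- data.frame(
      s_chrom = "mchrI", s_start = 0L, s_end = 100000L, t_chrom = "hchrI",
      t_strand = "+", t_size = 100000L, t_start = 0L,
      stringsAsFactors = FALSE)
    next_id <- next_id + 1L
  }
  blocks <- do.call(rbind, blocks)
  tgt_sizes <- stats::setNames(
    vapply(split(blocks$t_size, blocks$t_chrom), max, numeric(1)),
    NULL)
  names(tgt_sizes) <- sort(unique(blocks$t_chrom))
  tgt_sizes <- vapply(names(tgt_sizes), function(tc)
    max(blocks$t_size[blocks$t_chrom == tc]), numeric(1))

  # ---- interactions with planted truth ----
  ns <- nrow(slots)
  jit <- function(x) if (cfg$anchor_jitter_bp > 0)
    x + sample(-cfg$anchor_jitter_bp:cfg$anchor_jitter_bp, length(x),
               replace = TRUE) else x
  p_start <- jit(slots$offset + cfg$p_off); p_end <- p_start + al
  e_start <- jit(slots$offset + cfg$e_off); e_end <- e_start + al
  inter <- data.frame(
    id = sprintf("wTR%d_%d", (seq_len(ns) - 1L) %% 3L + 1L, 1000L + seq_len(ns)),
    replicate = sprintf("wTR%d", (seq_len(ns) - 1L) %% 3L + 1L),
    pet_count = sample(2:40, ns, replace = TRUE),
    chrom = slots$chrom, p_start = p_start, p_end = p_end,
    e_chrom = slots$chrom, e_start = e_start, e_end = e_end,
    enhancer_state = ifelse(seq_len(ns) %% 3L == 0L, "poised", "active"),
    truth_class = slots$class, stringsAsFactors = FALSE)
  tmap <- function(chrom, a, b) {
    m <- .truth_map(blocks, chrom, a, b)
    if (is.null(m)) list(chrom = NA_character_, start = NA_integer_,
                         end = NA_integer_) else m
  }
  pt <- lapply(seq_len(ns), function(i) {
    if (inter$truth_class[i] %in% c("P_plus_E", "split", "P_only"))
      tmap(inter$chrom[i], inter$p_start[i], inter$p_end[i])
    else list(chrom = NA_character_, start = NA_integer_, end = NA_integer_)
  })
  et <- lapply(seq_len(ns), function(i) {
    if (inter$truth_class[i] %in% c("P_plus_E", "split", "E_only"))
      tmap(inter$e_chrom[i], inter$e_start[i], inter$e_end[i])
    else list(chrom = NA_character_, start = NA_integer_, end = NA_integer_)
  })
  inter$t_p_chrom <- vapply(pt, `[[`, character(1), "chrom")
  inter$t_p_start <- vapply(pt, `[[`, integer(1), "start")
  inter$t_p_end <- vapply(pt, `[[`, integer(1), "end")
  inter$t_e_chrom <- vapply(et, `[[`, character(1), "chrom")
  inter$t_e_start <- vapply(et, `[[`, integer(1), "start")
  inter$t_e_end <- vapply(et, `[[`, integer(1), "end")

  # ---- gene models ----
  tss_off <- cfg$p_off + al %/% 2L
  genes_source <- data.frame(
    gene_id = sprintf("mG%03d", seq_len(ns)), chrom = slots$chrom,
    strand = "+", tss = slots$offset + tss_off,
    start = slots$offset + tss_off,
    end = slots$offset + tss_off + cfg$gene_len, stringsAsFactors = FALSE)
  host <- which(seq_len(ns) %% cfg$genic_enhancer_every == 0L)
  if (length(host))
    genes_source <- rbind(genes_source, data.frame(
      gene_id = sprintf("mH%03d", host), chrom = slots$chrom[host],
      strand = "+", tss = slots$offset[host] + cfg$e_off - 4000L,
      start = slots$offset[host] + cfg$e_off - 4000L,
      end = slots$offset[host] + cfg$e_off + cfg$gene_len,
      stringsAsFactors = FALSE))
  add_exons <- function(g) {
    g$exon_starts <- paste(g$start, g$end - 200L, sep = ",")
    g$exon_ends <- paste(g$start + 200L, g$end, sep = ",")
    g
  }
  genes_source <- add_exons(genes_source)

  gm <- which(!is.na(inter$t_p_chrom))  # slots whose gene body mapped
  genes_target <- do.call(rbind, lapply(gm, function(i) {
    m <- tmap(inter$chrom[i], slots$offset[i] + tss_off,
              slots$offset[i] + tss_off + cfg$gene_len)
    rev_strand <- m$start != .truth_map(blocks, inter$chrom[i],
                                        slots$offset[i] + tss_off,
                                        slots$offset[i] + tss_off + 1L)$start
    data.frame(gene_id = sprintf("GENE%03d", i), chrom = m$chrom,
               strand = if (rev_strand) "-" else "+",
               tss = if (rev_strand) m$end - 1L else m$start,
               start = m$start, end = m$end, stringsAsFactors = FALSE)
  }))
  inter$connected_gene <- ifelse(!is.na(inter$t_p_chrom),
                                 sprintf("GENE%03d", seq_len(ns)),
                                 NA_character_)
  # intervening target-side genes (spans_multiple_genes truth)
  ppe <- which(inter$truth_class == "P_plus_E")
  spans_truth <- stats::setNames(rep(FALSE, ns), inter$id)
  ivg <- ppe[seq_along(ppe) %% cfg$spans_genes_every == 0L]
  if (length(ivg)) {
    genes_target <- rbind(genes_target, do.call(rbind, lapply(ivg, function(i) {
      lo <- min(inter$t_p_end[i], inter$t_e_end[i])
      hi <- max(inter$t_p_start[i], inter$t_e_start[i])
      mid <- (lo + hi) %/% 2L
      data.frame(gene_id = sprintf("IVG%03d", i), chrom = inter$t_p_chrom[i],
                 strand = "+", tss = mid - 1500L, start = mid - 1500L,
                 end = mid + 1500L, stringsAsFactors = FALSE)
    })))
    spans_truth[inter$id[ivg]] <- TRUE
  }
  genes_target <- add_exons(genes_target)

  # ---- source histone peaks ----
  peaks_source <- rbind(
    data.frame(chrom = inter$e_chrom, start = inter$e_start + 200L,
               end = inter$e_start + 900L, mark = "H3K4me1"),
    with(inter[inter$enhancer_state == "active", ],
         data.frame(chrom = e_chrom, start = e_start + 600L,
                    end = e_start + 1300L, mark = "H3K27Ac")),
    # decoy fragments below the minimum mark length, away from anchors
    data.frame(chrom = slots$chrom[slots$k %% 5L == 0L],
               start = slots$offset[slots$k %% 5L == 0L] + 40000L,
               end = slots$offset[slots$k %% 5L == 0L] + 40200L,
               mark = "H3K4me1"))

  # ---- target-side layers over the both-anchor (P_plus_E) set ----
  ppe_ids <- inter$id[ppe]
  enh_t <- data.frame(id = inter$id[ppe], chrom = inter$t_e_chrom[ppe],
                      start = inter$t_e_start[ppe], end = inter$t_e_end[ppe],
                      state = inter$enhancer_state[ppe],
                      stringsAsFactors = FALSE)
  peak_layers <- list(); tissue_truth <- list()
  for (tissue in names(cfg$k4me1_match_frac)) {
    m <- sort(sample(nrow(enh_t),
                     round(cfg$k4me1_match_frac[[tissue]] * nrow(enh_t))))
    k4 <- data.frame(chrom = enh_t$chrom[m], start = enh_t$start[m] + 100L,
                     end = enh_t$start[m] + 700L)
    layer <- list(H3K4me1 = k4)
    if (tissue %in% cfg$k27ac_tissues) {
      ma <- m[enh_t$state[m] == "active"]
      layer$H3K27Ac <- data.frame(chrom = enh_t$chrom[ma],
                                  start = enh_t$start[ma] + 100L,
                                  end = enh_t$start[ma] + 700L)
    }
    peak_layers[[tissue]] <- layer
    tissue_truth[[tissue]] <- enh_t$id[m]
  }

  # ---- TADs ----
  span_lo <- pmin(inter$t_p_start[ppe], inter$t_e_start[ppe])
  span_hi <- pmax(inter$t_p_end[ppe], inter$t_e_end[ppe])
  tad_sets <- list(tad_A = data.frame(chrom = inter$t_p_chrom[ppe],
                                      start = span_lo - 2000L,
                                      end = span_hi + 2000L))
  np <- length(ppe)
  n_intra <- floor(cfg$tad_intra_frac * np)
  n_inter <- floor(cfg$tad_inter_frac * np)
  tad_b <- list(); tad_b_truth <- character(np)
  for (j in seq_len(np)) {
    i <- ppe[j]
    if (j <= n_intra) {
      tad_b_truth[j] <- "intra"
      tad_b[[length(tad_b) + 1L]] <- data.frame(
        chrom = inter$t_p_chrom[i], start = span_lo[j] - 2000L,
        end = span_hi[j] + 2000L)
    } else if (j <= n_intra + n_inter) {
      tad_b_truth[j] <- "inter"
      left_end <- min(inter$t_p_end[i], inter$t_e_end[i])
      right_start <- max(inter$t_p_start[i], inter$t_e_start[i])
      bnd <- (left_end + right_start) %/% 2L
      tad_b[[length(tad_b) + 1L]] <- data.frame(
        chrom = rep(inter$t_p_chrom[i], 2),
        start = c(span_lo[j] - 2000L, bnd), end = c(bnd, span_hi[j] + 2000L))
    } else tad_b_truth[j] <- "outside"
  }
  tad_sets$tad_B <- if (length(tad_b)) do.call(rbind, tad_b)
    else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  tad_truth <- list(tad_A = stats::setNames(rep("intra", np), inter$id[ppe]),
                    tad_B = stats::setNames(tad_b_truth, inter$id[ppe]))

  # ---- loop datasets ----
  loop_sets <- list(); loop_truth <- list()
  if (np > 0 && length(cfg$loop_cov)) {
    nms <- names(cfg$loop_cov)
    nA <- round(cfg$loop_cov[[1]] * np)
    setA <- sort(sample(np, nA))
    loop_truth[[nms[1]]] <- inter$id[ppe][setA]
    sets <- list(setA)
    if (length(nms) > 1) {
      for (d in 2:length(nms)) {
        nB <- round(cfg$loop_cov[[d]] * np)
        n_shared <- min(round(cfg$loop_redundancy * nB), nA)
        shared <- sample(setA, n_shared)
        pool <- setdiff(seq_len(np), setA)
        fresh <- if (nB - n_shared > 0)
          sample(pool, min(nB - n_shared, length(pool))) else integer(0)
        setB <- sort(c(shared, fresh))
        loop_truth[[nms[d]]] <- inter$id[ppe][setB]
        sets[[d]] <- setB
      }
    }
    for (d in seq_along(nms)) {
      idx <- ppe[sets[[d]]]
      swap <- seq_along(idx) %% 2L == 0L  # half written enhancer-first
      loop_sets[[nms[d]]] <- data.frame(
        chrom1 = inter$t_p_chrom[idx],
        start1 = ifelse(swap, inter$t_e_start[idx] - 500L,
                        inter$t_p_start[idx] - 500L),
        end1 = ifelse(swap, inter$t_e_end[idx] + 500L,
                      inter$t_p_end[idx] + 500L),
        chrom2 = inter$t_e_chrom[idx],
        start2 = ifelse(swap, inter$t_p_start[idx] - 500L,
                        inter$t_e_start[idx] - 500L),
        end2 = ifelse(swap, inter$t_p_end[idx] + 500L,
                      inter$t_e_end[idx] + 500L),
        stringsAsFactors = FALSE)
    }
  }

  # ---- conservation track (target genome) ----
  fg <- enh_t[, c("chrom", "start", "end")]
  cons <- list()
  for (tc in names(tgt_sizes)) {
    full <- IRanges::IRanges(1L, as.integer(tgt_sizes[[tc]]))
    fgc <- fg[fg$chrom == tc, , drop = FALSE]
    fgr <- IRanges::reduce(IRanges::IRanges(fgc$start + 1L, fgc$end))
    bgr <- IRanges::setdiff(full, fgr)
    cons[[length(cons) + 1L]] <- rbind(
      if (length(bgr)) data.frame(chrom = tc, start = IRanges::start(bgr) - 1L,
                                  end = IRanges::end(bgr),
                                  score = cfg$conservation_bg),
      if (length(fgr)) data.frame(chrom = tc, start = IRanges::start(fgr) - 1L,
                                  end = IRanges::end(fgr),
                                  score = cfg$conservation_fg))
  }
  conservation <- .sort_bed(do.call(rbind, cons))

  # ---- target genome sequence ----
  target_seq <- lapply(tgt_sizes, .rand_dna)
  names(target_seq) <- names(tgt_sizes)

  # ---- risk variants and PWMs ----
  traits <- c("SCZ", "BP", "I")
  variants <- NULL; pwms <- list(); motif_truth <- NULL
  if (np > 0 && cfg$n_variants_in > 0) {
    vi <- ppe[((seq_len(cfg$n_variants_in) - 1L) %% np) + 1L]
    pos_in <- inter$t_e_start[vi] + 1000L + 1L  # 1-based, enhancer center
    pos_in <- pos_in + cumsum(duplicated(vi)) * 50L  # separate re-used slots
    vchrom <- inter$t_e_chrom[vi]
    n_motif <- min(3L, cfg$n_variants_in)
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(n_motif)) {
      consensus <- sample(bases, 8L, replace = TRUE)
      mat <- matrix(0.01, nrow = 8, ncol = 4,
                    dimnames = list(NULL, bases))
      mat[cbind(1:8, match(consensus, bases))] <- 0.97
      pwms[[j]] <- pwm_motif(sprintf("MOTIF%d", j), sprintf("TF%d", j), mat)
      w <- pos_in[j] - 3L  # variant sits at motif position 4
      planted <- consensus
      effect <- if (j < 3L) "lost" else "gained"
      if (effect == "gained")
        planted[4] <- sample(setdiff(bases, consensus[4]), 1)
      sq <- target_seq[[vchrom[j]]]
      substr(sq, w, w + 7L) <- paste(planted, collapse = "")
      target_seq[[vchrom[j]]] <- sq
      motif_truth <- rbind(motif_truth, data.frame(
        rsid = sprintf("rs%06d", j), motif_id = sprintf("MOTIF%d", j),
        expected_effect = effect, consensus_base = consensus[4],
        stringsAsFactors = FALSE))
    }
    n_all <- cfg$n_variants_in + cfg$n_variants_lowppa + cfg$n_variants_out
    low_i <- ppe[((seq_len(cfg$n_variants_lowppa) - 1L) %% np) + 1L]
    out_chrom <- names(tgt_sizes)[1]
    variants <- data.frame(
      rsid = sprintf("rs%06d", seq_len(n_all)),
      chrom = c(vchrom, inter$t_e_chrom[low_i],
                rep(out_chrom, cfg$n_variants_out)),
      pos = c(pos_in, inter$t_e_start[low_i] + 300L + 1L,
              400L + seq_len(cfg$n_variants_out) * 150L),
      trait = sample(traits, n_all, replace = TRUE),
      ppa = c(stats::runif(cfg$n_variants_in, 0.02, 0.6),
              rep(0.005, cfg$n_variants_lowppa),
              stats::runif(cfg$n_variants_out, 0.02, 0.6)),
      in_enhancer = rep(c(TRUE, FALSE, FALSE),
                        c(cfg$n_variants_in, cfg$n_variants_lowppa,
                          cfg$n_variants_out)),
      stringsAsFactors = FALSE)
    variants$in_enhancer[cfg$n_variants_in + seq_len(cfg$n_variants_lowppa)] <- TRUE
    variants$ref <- vapply(seq_len(n_all), function(i)
      substr(target_seq[[variants$chrom[i]]], variants$pos[i],
             variants$pos[i]), character(1))
    bases <- c("A", "C", "G", "T")
    variants$alt <- vapply(seq_len(n_all), function(i) {
      if (i <= nrow(motif_truth)) {
        if (motif_truth$expected_effect[i] == "gained")
          motif_truth$consensus_base[i]
        else sample(setdiff(bases, variants$ref[i]), 1)
      } else sample(setdiff(bases, variants$ref[i]), 1)
    }, character(1))
  }

  # ---- cCREs on the source enhancers ----
  subclasses <- c("RGL", "OPC", "ASC", "OGC", "GABA", "GLUT")
  cov_i <- sort(sample(ns, round(cfg$ccre_frac * ns)))
  ccres <- do.call(rbind, lapply(cov_i, function(i) {
    k <- sample(1:2, 1)
    data.frame(chrom = inter$e_chrom[i],
               start = inter$e_start[i] + c(200L, 1100L)[seq_len(k)],
               end = inter$e_start[i] + c(800L, 1700L)[seq_len(k)],
               ccre_id = sprintf("cCRE_%03d_%d", i, seq_len(k)),
               subclass = sample(subclasses, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  ccre_truth_ids <- inter$id[cov_i]

  # ---- validated-enhancer (in-vivo) elements on the target ----
  vista <- NULL
  if (np > 0) {
    n_in <- min(cfg$vista_pos_in, np)
    vi2 <- ppe[seq_len(n_in)]
    bg_chrom <- names(tgt_sizes)[1]
    bg_size <- as.integer(tgt_sizes[[bg_chrom]])
    vista <- rbind(
      if (n_in) data.frame(chrom = inter$t_e_chrom[vi2],
                           start = inter$t_e_start[vi2] + 400L,
                           end = inter$t_e_start[vi2] + 1600L,
                           element_id = sprintf("VP_%03d", seq_len(n_in)),
                           label = "positive"),
      if (cfg$vista_pos_out) data.frame(
        chrom = bg_chrom,
        start = bg_size - 2900L + seq_len(cfg$vista_pos_out) * 400L,
        end = bg_size - 2900L + seq_len(cfg$vista_pos_out) * 400L + 300L,
        element_id = sprintf("VP_%03d", n_in + seq_len(cfg$vista_pos_out)),
        label = "positive"),
      if (cfg$vista_neg) data.frame(
        chrom = bg_chrom, start = 100L + seq_len(cfg$vista_neg) * 250L,
        end = 100L + seq_len(cfg$vista_neg) * 250L + 200L,
        element_id = sprintf("VN_%03d", seq_len(cfg$vista_neg)),
        label = "negative"))
  }

  # ---- gene-disease panels ----
  all_genes <- genes_target$gene_id
  conf_levels <- c("definitive", "strong", "moderate", "supportive",
                   "limited", "disputed", "refuted", "animal")
  gene_panels <- list(
    DD = data.frame(gene = sample(all_genes, ceiling(0.6 * length(all_genes))),
                    confidence = sample(conf_levels,
                                        ceiling(0.6 * length(all_genes)),
                                        replace = TRUE),
                    stringsAsFactors = FALSE),
    Eye = data.frame(gene = sample(all_genes, ceiling(0.3 * length(all_genes))),
                     confidence = sample(conf_levels,
                                         ceiling(0.3 * length(all_genes)),
                                         replace = TRUE),
                     stringsAsFactors = FALSE))

  world <- structure(list(
    config = cfg, seed = cfg$seed,
    source_chrom_sizes = src_sizes,
    target_chrom_sizes = stats::setNames(as.integer(tgt_sizes),
                                         names(tgt_sizes)),
    chains = chains, blocks = blocks,
    genes_source = genes_source, genes_target = genes_target,
    interactions = inter,
    peaks_source = peaks_source,
    peak_layers = peak_layers,
    tad_sets = tad_sets, loop_sets = loop_sets,
    conservation = conservation,
    variants = variants, pwms = pwms,
    ccres = ccres, vista = vista, gene_panels = gene_panels,
    target_seq = target_seq,
    truth = list(class = stats::setNames(inter$truth_class, inter$id),
                 spans_multiple = spans_truth,
                 tissue_matched = tissue_truth,
                 tad = tad_truth, loops = loop_truth,
                 ccre_ids = ccre_truth_ids,
                 motifs = motif_truth)
  ), class = "synthetic_world")
  plant_cnv_enrichment(world,
                       odds_ratio = cfg$cnv$odds_ratio,
                       n_case = cfg$cnv$n_case,
                       n_control = cfg$cnv$n_control,
                       seed = cfg$seed + 1000L)
}

#' Plant case/control CNV cohorts with a chosen enrichment odds ratio
#'
#' Control CNVs overlap the remapped-interaction regions at the baseline
#' rate `p_control` (from the world's configuration); case CNVs at the rate
#' whose odds are `odds_ratio` times the control odds.  Overlapping
#' placements target one interaction's enhancer (or, with probability
#' `span_frac`, its whole promoter-enhancer span); non-overlapping
#' placements are drawn from the genomic background away from any
#' interaction anchor.  The realized 2x2 table is recorded in the world.
#'
#' @param world a `synthetic_world`.
#' @param odds_ratio case/control odds ratio of overlapping (> 0).
#' @param n_case,n_control cohort sizes.
#' @param seed integer seed.
#' @return the world with `cnv_case`, `cnv_control` and `cnv_table` set.
#' @export
plant_cnv_enrichment <- function(world, odds_ratio = 5, n_case = 500L,
                                 n_control = 500L, seed = world$seed + 1000L) {
  stopifnot(odds_ratio > 0)
  set.seed(seed)
  cfg <- world$config$cnv
  inter <- world$interactions
  ppe <- which(inter$truth_class == "P_plus_E")
  if (!length(ppe)) stop("no both-anchor interactions to target")
  p0 <- cfg$p_control
  p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
  regions <- rbind(
    data.frame(chrom = inter$t_e_chrom[ppe], start = inter$t_e_start[ppe],
               end = inter$t_e_end[ppe]),
    data.frame(chrom = inter$t_p_chrom[ppe], start = inter$t_p_start[ppe],
               end = inter$t_p_end[ppe]))
  # background space: gaps of the target genome clear of any anchor,
  # padded so a background CNV cannot touch one
  pad <- max(cfg$len_background, cfg$len_hit) + 100L
  gaps <- list()
  for (tc in names(world$target_chrom_sizes)) {
    sz <- world$target_chrom_sizes[[tc]]
    sub <- regions[regions$chrom == tc, , drop = FALSE]
    occ <- IRanges::reduce(IRanges::IRanges(pmax(1L, sub$start + 1L - pad),
                                            pmin(sz, sub$end + pad)))
    free <- IRanges::setdiff(IRanges::IRanges(1L, sz), occ)
    free <- free[IRanges::width(free) > cfg$len_background + 2L]
    if (length(free))
      gaps[[length(gaps) + 1L]] <- data.frame(
        chrom = tc, start = IRanges::start(free) - 1L,
        end = IRanges::end(free))
  }
  gaps <- do.call(rbind, gaps)
  if (is.null(gaps) || nrow(gaps) == 0)
    stop("no background space left for non-overlapping CNV placement")
  draw_cohort <- function(n_subj, p_hit, cohort) {
    hit <- stats::runif(n_subj) < p_hit
    tgt <- sample(ppe, n_subj, replace = TRUE)
    span <- stats::runif(n_subj) < cfg$span_frac
    gp <- sample(nrow(gaps), n_subj, replace = TRUE,
                 prob = gaps$end - gaps$start - cfg$len_background)
    bg_start <- gaps$start[gp] + floor(stats::runif(n_subj) *
      (gaps$end[gp] - gaps$start[gp] - cfg$len_background))
    e_mid <- (inter$t_e_start[tgt] + inter$t_e_end[tgt]) %/% 2L
    lo <- pmin(inter$t_p_start[tgt], inter$t_e_start[tgt]) - 1000L
    hi <- pmax(inter$t_p_end[tgt], inter$t_e_end[tgt]) + 1000L
    chrom <- ifelse(hit, inter$t_e_chrom[tgt], gaps$chrom[gp])
    start <- ifelse(hit, ifelse(span, lo, e_mid - cfg$len_hit %/% 2L),
                    bg_start)
    end <- ifelse(hit, ifelse(span, hi, e_mid + cfg$len_hit %/% 2L),
                  bg_start + cfg$len_background)
    data.frame(
      chrom = chrom, start = pmax(0L, as.integer(start)),
      end = as.integer(end),
      cnv_type = sample(c("gain", "loss"), n_subj, replace = TRUE),
      cohort = cohort,
      phenotype = sample(c("ASD", "ADHD", "SCZ", "OCD", "DD"), n_subj,
                         replace = TRUE),
      subject_id = sprintf("%s_%04d", cohort, seq_len(n_subj)),
      pathogenicity_class = sample(c("benign", "VUS", "pathogenic"), n_subj,
                                   replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      planted_hit = hit, stringsAsFactors = FALSE)
  }
  case <- draw_cohort(n_case, p1, "case")
  ctrl <- draw_cohort(n_control, p0, "control")
  if (sum(case$planted_hit) + sum(ctrl$planted_hit) == 0)
    warning("cohorts too small to realize any overlap")
  world$cnv_case <- case
  world$cnv_control <- ctrl
  world$cnv_table <- matrix(
    c(sum(case$planted_hit), sum(!case$planted_hit),
      sum(ctrl$planted_hit), sum(!ctrl$planted_hit)),
    nrow = 2, dimnames = list(c("overlap", "no_overlap"),
                              c("case", "control")))
  world
}
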