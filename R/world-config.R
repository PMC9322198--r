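# Generator configuration for the synthetic paired-genome world.

#' Configuration for the synthetic world generator
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 10 interactions per synteny class, 2 kb anchors about 18 kb
#' apart, a 0.4 retained fraction for partially deleted anchors (below the
#' 0.5 liftover minMatch), four target-side tissue layers with H3K4me1
#' match fractions inside the empirically typical 80-94% range, two loop
#' datasets at 30% coverage each with 50% redundancy, and CNV cohorts of
#' 500 case / 500 control subjects with a control hit rate of 0.30 and a
#' planted case odds ratio of 5.
#'
#' @param n_per_class named integer vector: interactions per planted
#'   synteny class (`P_plus_E`, `split`, `E_only`, `P_only`, `lost`).
#' @param seed integer seed driving all generation.
#' @param anchor_len anchor length in bp.
#' @param partial_keep_frac fraction of a partially deleted anchor that
#'   stays aligned (must be < 0.5 so the anchor fails the minMatch filter).
#' @param anchor_jitter_bp uniform jitter applied to planted anchor
#'   positions (0 = clean planting; nonzero breaks the truth guarantee).
#' @param k4me1_match_frac named numeric vector: per-tissue fraction of
#'   remapped enhancers carrying a planted H3K4me1 peak.
#' @param k27ac_tissues tissues that additionally get an H3K27Ac layer.
#' @param loop_cov named numeric vector: per-dataset fraction of remapped
#'   interactions represented by a planted loop.
#' @param loop_redundancy fraction of the second dataset's loops shared
#'   with the first.
#' @param tad_intra_frac,tad_inter_frac composition of the second TAD
#'   dataset (the first covers every interaction intra-TAD); the remainder
#'   is left outside any TAD.
#' @param conservation_fg,conservation_bg per-base conservation scores
#'   planted on remapped enhancers vs the genomic background.
#' @param n_variants_in,n_variants_out,n_variants_lowppa risk variants
#'   planted inside remapped enhancers, in background DNA, and inside
#'   enhancers but below the posterior-probability cutoff.
#' @param ccre_frac fraction of source enhancers covered by a planted
#'   candidate cis-regulatory element.
#' @param vista_pos_in,vista_pos_out,vista_neg planted validated-enhancer
#'   elements: positives overlapping remapped enhancers, positives in
#'   background, negatives.
#' @param cnv list of CNV-cohort parameters: `odds_ratio`, `n_case`,
#'   `n_control`, `p_control` (control overlap rate), `len_hit` (CNV length
#'   for enhancer-targeted placements), `len_span` (length for placements
#'   spanning both anchors), `span_frac`, `len_background`.
#' @param genic_enhancer_every every k-th slot hosts its enhancer inside a
#'   gene body (exercising the `genic` anchor class).
#' @param spans_genes_every every k-th both-anchor slot gets an intervening
#'   target-side gene between promoter and enhancer.
#' @param identity_chrom when TRUE, adds one source chromosome copied
#'   verbatim to one target chromosome (identity liftover fixture).
#' @return a `world_config` list.
#' @export
world_config <- function(n_per_class = c(P_plus_E = 10L, split = 10L,
                                         E_only = 10L, P_only = 10L,
                                         lost = 10L),
                         seed = 1L,
                         anchor_len = 2000L,
                         partial_keep_frac = 0.4,
                         anchor_jitter_bp = 0L,
                         k4me1_match_frac = c(fetal_cortex = 0.90,
                                              adult_pfc = 0.94,
                                              hippocampus = 0.80,
                                              neural_progenitor = 0.85),
                         k27ac_tissues = c("adult_pfc", "fetal_cortex"),
                         loop_cov = c(loops_A = 0.3, loops_B = 0.3),
                         loop_redundancy = 0.5,
                         tad_intra_frac = 0.8, tad_inter_frac = 0.1,
                         conservation_fg = 0.9, conservation_bg = 0.1,
                         n_variants_in = 5L, n_variants_out = 5L,
                         n_variants_lowppa = 3L,
                         ccre_frac = 0.955,
                         vista_pos_in = 2L, vista_pos_out = 3L,
                         vista_neg = 3L,
                         cnv = list(odds_ratio = 5, n_case = 500L,
                                    n_control = 500L, p_control = 0.3,
                                    len_hit = 5000L, len_span = 40000L,
                                    span_frac = 0.3,
                                    len_background = 5000L),
                         genic_enhancer_every = 3L,
                         spans_genes_every = 2L,
                         identity_chrom = FALSE) {
  cfg <- list(n_per_class = n_per_class, seed = as.integer(seed),
              anchor_len = as.integer(anchor_len),
              partial_keep_frac = partial_keep_frac,
              anchor_jitter_bp = as.integer(anchor_jitter_bp),
              k4me1_match_frac = k4me1_match_frac,
              k27ac_tissues = k27ac_tissues,
              loop_cov = loop_cov, loop_redundancy = loop_redundancy,
              tad_intra_frac = tad_intra_frac,
              tad_inter_frac = tad_inter_frac,
              conservation_fg = conservation_fg,
              conservation_bg = conservation_bg,
              n_variants_in = as.integer(n_variants_in),
              n_variants_out = as.integer(n_variants_out),
              n_variants_lowppa = as.integer(n_variants_lowppa),
              ccre_frac = ccre_frac,
              vista_pos_in = as.integer(vista_pos_in),
              vista_pos_out = as.integer(vista_pos_out),
              vista_neg = as.integer(vista_neg),
              cnv = cnv,
              genic_enhancer_every = as.integer(genic_enhancer_every),
              spans_genes_every = as.integer(spans_genes_every),
              identity_chrom = identity_chrom,
              # fixed slot geometry (bp)
              slot_len = 50000L, margin = 5000L, insert_len = 1000L,
              p_off = 10000L, e_off = 30000L, gene_len = 6000L)
  class(cfg) <- "world_config"
  validate_world_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the feasibility of the slot geometry: anchors and their deletion
#' windows must fit inside their slot without touching each other or the
#' promoter window of the slot gene.
#' @param cfg a `world_config`.
#' @return `cfg`, invisibly; errors name the violated constraint.
#' @export
validate_world_config <- function(cfg) {
  expected <- c("P_plus_E", "split", "E_only", "P_only", "lost")
  if (!all(expected %in% names(cfg$n_per_class)))
    stop("n_per_class must name all of: ", paste(expected, collapse = ", "))
  if (any(cfg$n_per_class < 0)) stop("n_per_class entries must be >= 0")
  if (cfg$anchor_len < 100L)
    stop("infeasible configuration: anchor_len < 100 bp")
  if (cfg$partial_keep_frac <= 0 || cfg$partial_keep_frac >= 0.5)
    stop("infeasible configuration: partial_keep_frac must be in (0, 0.5) ",
         "so partially deleted anchors fail the minMatch filter")
  tss <- cfg$p_off + cfg$anchor_len %/% 2L
  del_pad <- 1000L
  p_hi <- cfg$p_off + cfg$anchor_len + del_pad
  if (tss + 2500L >= cfg$e_off - del_pad)
    stop("infeasible configuration: promoter window or its deletion pad ",
         "reaches the enhancer anchor (blocks would overlap)")
  if (cfg$e_off + cfg$anchor_len + del_pad >= cfg$slot_len)
    stop("infeasible configuration: enhancer anchor does not fit its slot")
  if (p_hi >= cfg$e_off)
    stop("infeasible configuration: promoter and enhancer blocks overlap")
  invisible(cfg)
}
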