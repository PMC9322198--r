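# Risk-variant overlap, PWM disruption scoring, CNV overlap and
# enrichment, and gene-panel joins.

hms_fixture <- function() {
  data.frame(
    id = sprintf("wTR1_%d", 1:5),
    p_chrom = "c1", p_start = seq(1000L, 81000L, 20000L),
    p_end = seq(3000L, 83000L, 20000L),
    e_chrom = "c1", e_start = seq(10000L, 90000L, 20000L),
    e_end = seq(12000L, 92000L, 20000L),
    connected_gene = "TRIM8", stringsAsFactors = FALSE)
}

test_that("variant hits respect the interval boundary and PPA threshold", {
  hms <- hms_fixture()
  variants <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "c1",
    # 1-based positions: first base of enhancer 1, one before it,
    # inside enhancer 2 (but PPA at exactly the threshold), last base of 3
    pos = c(10001L, 10000L, 30500L, 52000L),
    ref = "A", alt = "G", trait = "SCZ",
    ppa = c(0.05, 0.05, 0.01, 0.2), stringsAsFactors = FALSE)
  hits <- variants_in_enhancers(variants, hms)
  expect_equal(sort(hits$rsid), c("rs1", "rs4"))
  expect_equal(hits$id[hits$rsid == "rs1"], "wTR1_1")
  expect_equal(hits$id[hits$rsid == "rs4"], "wTR1_3")
})

test_that("five variants in five enhancers connect to one gene", {
  hms <- hms_fixture()
  variants <- data.frame(
    rsid = sprintf("rs%d", 1:5), chrom = "c1",
    pos = seq(11000L, 91000L, 20000L), ref = "A", alt = "G",
    trait = "SCZ", ppa = 0.1, stringsAsFactors = FALSE)
  hits <- variants_in_enhancers(variants, hms)
  expect_equal(nrow(hits), 5)
  expect_equal(length(unique(hits$id)), 5)
  expect_equal(unique(hits$connected_gene), "TRIM8")
})

test_that("variant hit totals are order-invariant and consistent", {
  hms <- hms_fixture()
  set.seed(41)
  variants <- data.frame(
    rsid = sprintf("rs%d", 1:40), chrom = "c1",
    pos = sample(1:95000, 40), ref = "A", alt = "G", trait = "BP",
    ppa = runif(40, 0.005, 0.5), stringsAsFactors = FALSE)
  h1 <- variants_in_enhancers(variants, hms)
  h2 <- variants_in_enhancers(variants[sample(40), ], hms)
  expect_identical(h1, h2)
  per_var <- table(h1$rsid); per_enh <- table(h1$id)
  expect_equal(sum(per_var), nrow(h1))
  expect_equal(sum(per_enh), nrow(h1))
})

test_that("the worked consensus-PWM example scores exactly", {
  # 4-long motif ACGT with p = 0.97 on consensus, pseudocount 0.01,
  # uniform background: consensus term log2(0.98/0.25), mismatch term
  # log2(0.02/0.25); G>T at motif position 3
  mat <- matrix(0.01, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(1:4, c(1, 2, 3, 4))] <- 0.97
  pwm <- pwm_motif("M1", "TF1", mat)
  genome <- list(cX = paste0(strrep("A", 20), "ACGT", strrep("A", 20)))
  variant <- list(chrom = "cX", pos = 23L, ref = "G", alt = "T",
                  rsid = "rsX")
  r <- score_motif_disruption(variant, genome, pwm, effect_threshold = 1)
  cons_term <- log2(0.98 / 0.25); mis_term <- log2(0.02 / 0.25)
  expect_equal(r$best_ref_score, 4 * cons_term, tolerance = 1e-12)
  expect_equal(r$best_alt_score, 3 * cons_term + mis_term, tolerance = 1e-12)
  expect_equal(r$delta, -(cons_term - mis_term), tolerance = 1e-12)
  expect_equal(r$delta, -5.6148, tolerance = 1e-4)
  expect_equal(r$effect, "lost")
})

test_that("a uniform matrix is neutral and scoring is strand-symmetric", {
  uni <- pwm_motif("U", "U", matrix(0.25, 6, 4))
  genome <- list(cX = paste0(strrep("C", 10), "GATTAC", strrep("C", 10)))
  v <- list(chrom = "cX", pos = 13L, ref = "T", alt = "G", rsid = "rs0")
  r <- score_motif_disruption(v, genome, uni)
  expect_equal(r$delta, 0)
  expect_equal(r$effect, "neutral")
  # reverse-complement the genome: best scores are unchanged
  mat <- matrix(0.01, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  mat[cbind(1:6, c(3, 1, 4, 4, 1, 2))] <- 0.97  # GATTAC
  pwm <- pwm_motif("M2", "TF2", mat)
  fwd <- score_motif_disruption(v, genome, pwm)
  rc_seq <- paste(rev(unname(REVCOMP[strsplit(genome$cX, "")[[1]]])),
                  collapse = "")
  v_rc <- list(chrom = "cX", pos = nchar(rc_seq) - 13L + 1L,
               ref = "A", alt = "C", rsid = "rs0rc")
  rc <- score_motif_disruption(v_rc, list(cX = rc_seq), pwm)
  expect_equal(rc$best_ref_score, fwd$best_ref_score, tolerance = 1e-12)
  expect_equal(rc$best_alt_score, fwd$best_alt_score, tolerance = 1e-12)
})

test_that("a reference-allele mismatch is an error naming the position", {
  uni <- pwm_motif("U", "U", matrix(0.25, 4, 4))
  genome <- list(cX = "AAAAAAAA")
  v <- list(chrom = "cX", pos = 4L, ref = "C", alt = "G", rsid = "rs0")
  expect_error(score_motif_disruption(v, genome, uni), "cX:4")
})

test_that("best-window scores match the exhaustive oracle on random triples", {
  set.seed(51)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:200) {
    L <- sample(4:10, 1)
    mat <- matrix(runif(L * 4), L, 4, dimnames = list(NULL, bases))
    mat <- mat / rowSums(mat)
    pwm <- pwm_motif("R", "R", mat)
    seq_str <- paste(sample(bases, 60, replace = TRUE), collapse = "")
    pos <- sample(15:45, 1)
    ref <- substr(seq_str, pos, pos)
    alt <- sample(setdiff(bases, ref), 1)
    v <- list(chrom = "cX", pos = pos, ref = ref, alt = alt, rsid = "r")
    r <- score_motif_disruption(v, list(cX = seq_str), pwm)
    expect_equal(r$best_ref_score,
                 oracle_motif_best(seq_str, pos, ref, mat), tolerance = 1e-9)
    expect_equal(r$best_alt_score,
                 oracle_motif_best(seq_str, pos, alt, mat), tolerance = 1e-9)
  }
})

test_that("planted disrupting variants are called with their planted effect", {
  w <- default_world()
  genome <- w$target_seq
  truth <- w$truth$motifs
  for (i in seq_len(nrow(truth))) {
    v <- w$variants[w$variants$rsid == truth$rsid[i], ]
    pwm <- w$pwms[[which(vapply(w$pwms, `[[`, character(1), "motif_id") ==
                           truth$motif_id[i])]]
    r <- score_motif_disruption(v, genome, pwm)
    expect_equal(r$effect, truth$expected_effect[i])
  }
})

test_that("CNV overlap flags each anchor independently", {
  hms <- hms_fixture()
  cnvs <- data.frame(
    chrom = "c1",
    start = c(500L, 10500L, 400000L),
    end = c(15000L, 11000L, 401000L),
    cnv_type = "loss", cohort = "case", phenotype = "ASD",
    subject_id = c("s1", "s2", "s3"),
    pathogenicity_class = "VUS", stringsAsFactors = FALSE)
  ov <- cnv_overlap(cnvs, hms)
  # CNV 1 spans promoter and enhancer of wTR1_1; CNV 2 enhancer only;
  # CNV 3 hits nothing
  r1 <- ov[ov$subject_id == "s1" & ov$id == "wTR1_1", ]
  expect_true(r1$overlaps_enhancer && r1$overlaps_promoter)
  r2 <- ov[ov$subject_id == "s2", ]
  expect_equal(r2$id, "wTR1_1")
  expect_true(r2$overlaps_enhancer)
  expect_false(r2$overlaps_promoter)
  expect_false("s3" %in% ov$subject_id)
})

test_that("enhancer-only filtering and case-exclusivity behave as specified", {
  hms <- hms_fixture()
  case <- data.frame(
    chrom = "c1", start = c(500L, 10500L, 30500L),
    end = c(15000L, 11500L, 31500L), cnv_type = "loss", cohort = "case",
    phenotype = "ASD", subject_id = c("s1", "s2", "s3"),
    pathogenicity_class = "VUS", stringsAsFactors = FALSE)
  # control mirrors s3's CNV at 80% reciprocal overlap, same type
  ctrl <- data.frame(chrom = "c1", start = 30700L, end = 31700L,
                     cnv_type = "loss", cohort = "control",
                     phenotype = "none", subject_id = "c1",
                     pathogenicity_class = "benign", stringsAsFactors = FALSE)
  ov <- cnv_overlap(case, hms)
  eonly <- enhancer_only_disruptions(ov, control_cnvs = ctrl)
  # s1 covers E and P of wTR1_1: excluded for that record
  expect_false(any(eonly$subject_id == "s1" & eonly$id == "wTR1_1"))
  expect_true(eonly$case_exclusive[eonly$subject_id == "s2"])
  expect_false(eonly$case_exclusive[eonly$subject_id == "s3"])
})

test_that("the hypergeometric tail matches exact enumeration", {
  # N=20, K=10, n=10, k=9: P(X>=9) = 101/choose(20,10)
  expect_equal(stats::phyper(8, 10, 10, 10, lower.tail = FALSE),
               101 / choose(20, 10), tolerance = 1e-12)
  # package path on a constructed cohort reproducing that table
  hms <- data.frame(id = "r1", p_chrom = "c1", p_start = 1000L,
                    p_end = 2000L, e_chrom = "c1", e_start = 5000L,
                    e_end = 6000L, stringsAsFactors = FALSE)
  mk <- function(n_hit, n_miss, cohort) data.frame(
    chrom = "c1", start = c(rep(5100L, n_hit), rep(100000L, n_miss)),
    end = c(rep(5200L, n_hit), rep(100100L, n_miss)), cnv_type = "loss",
    cohort = cohort, phenotype = "x",
    subject_id = sprintf("%s%d", cohort, seq_len(n_hit + n_miss)),
    pathogenicity_class = "VUS", stringsAsFactors = FALSE)
  res <- hypergeometric_enrichment(mk(9, 1, "case"), mk(1, 9, "control"), hms)
  expect_equal(res[c("k", "n", "K", "N")],
               list(k = 9L, n = 10L, K = 10L, N = 20L))
  expect_equal(res$p_value, 101 / choose(20, 10), tolerance = 1e-12)
  # no-enrichment margins give p >= 0.5
  flat <- hypergeometric_enrichment(mk(5, 5, "case"), mk(5, 5, "control"), hms)
  expect_gte(flat$p_value, 0.5)
  # degenerate margins: p = 1 with a note
  expect_message(
    deg <- hypergeometric_enrichment(mk(0, 5, "case"), mk(0, 5, "control"),
                                     hms), "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("gene-panel joins keep duplicates and default to unknown", {
  panels <- list(
    DD = data.frame(gene = c("TRIM8", "TRIM8", "FOXP1"),
                    confidence = c("strong", "limited", "definitive")),
    Eye = data.frame(gene = "PAX6", confidence = "definitive"))
  res <- gene_panel_join(c("TRIM8", "NOVEL1"), panels)
  trim_dd <- res[res$gene == "TRIM8" & res$panel == "DD", ]
  expect_equal(sort(trim_dd$confidence), c("limited", "strong"))
  expect_equal(res$confidence[res$gene == "NOVEL1" & res$panel == "Eye"],
               "unknown")
})
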