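# Anchor classification, pair selection and enhancer-state calling.

genes_fix <- data.frame(
  gene_id = c("g1", "g2"), chrom = c("chrA", "chrA"), strand = "+",
  tss = c(10000L, 40000L), start = c(10000L, 40000L),
  end = c(20000L, 70000L), stringsAsFactors = FALSE)

test_that("anchors partition into promoter / genic / intergenic", {
  anchors <- data.frame(
    chrom = c("chrA", "chrA", "chrA"),
    start = c(8000L, 50000L, 90000L),
    end = c(8100L, 50400L, 90500L))
  cls <- classify_anchor(anchors, genes_fix)
  # [8000,8100) overlaps the promoter window [7500,12500) of g1;
  # [50000,50400) sits in the g2 body, 10 kb past its TSS window;
  # [90000,90500) touches nothing
  expect_equal(cls, c("promoter", "genic", "intergenic"))
  expect_equal(length(cls), nrow(anchors))
})

test_that("anchors on gene-free chromosomes are intergenic with a warning", {
  anchors <- data.frame(chrom = "chrEmpty", start = 0L, end = 100L)
  expect_warning(cls <- classify_anchor(anchors, genes_fix), "absent")
  expect_equal(cls, "intergenic")
})

test_that("widening the promoter window never demotes a promoter anchor", {
  set.seed(31)
  anchors <- data.frame(chrom = "chrA",
                        start = sample(0:99000, 200), end = 0L)
  anchors$end <- anchors$start + sample(100:3000, 200, replace = TRUE)
  narrow <- classify_anchor(anchors, genes_fix, promoter_halfwidth = 1000)
  wide <- classify_anchor(anchors, genes_fix, promoter_halfwidth = 5000)
  expect_true(all(wide[narrow == "promoter"] == "promoter"))
})

test_that("only promoter <-> non-promoter pairs are kept, promoter first", {
  pairs <- data.frame(
    chrom1 = "chrA", start1 = c(8000L, 8000L, 50000L, 90000L, 50000L, 8000L),
    end1 = c(8100L, 8100L, 50400L, 90100L, 50400L, 8100L),
    chrom2 = "chrA", start2 = c(90000L, 9000L, 8000L, 95000L, 60000L, 41000L),
    end2 = c(90500L, 9100L, 8100L, 95500L, 60400L, 41200L),
    id = paste0("wTR1_", 1:6), replicate = "wTR1", pet_count = 3L)
  c1 <- classify_anchor(pairs[, c("chrom1", "start1", "end1")] |>
                          setNames(c("chrom", "start", "end")), genes_fix)
  c2 <- classify_anchor(pairs[, c("chrom2", "start2", "end2")] |>
                          setNames(c("chrom", "start", "end")), genes_fix)
  expect_message(ep <- select_ep_pairs(pairs, c1, c2), "dropped")
  # pairs: (P,I)=keep, (P,P)=drop, (G,P)=keep swapped, (I,I)=drop,
  # (G,G)=drop, (P,P? [41000,41200) is inside g2 TSS window)=drop
  expect_equal(nrow(ep), 2)
  expect_equal(ep$id, c("wTR1_1", "wTR1_3"))
  # orientation normalized: promoter stored first
  expect_equal(ep$p_start, c(8000L, 8000L))
  expect_equal(ep$e_start, c(90000L, 50000L))
})

test_that("enhancer state follows the mark and reciprocal-overlap rules", {
  anchor <- data.frame(chrom = "chrA", start = 0L, end = 1000L)
  k4 <- data.frame(chrom = "chrA", start = 100L, end = 500L)
  k27 <- data.frame(chrom = "chrA", start = 400L, end = 800L)
  none <- k4[0, ]
  # marks co-overlap by 100 bp >= 10: active
  expect_equal(call_enhancer_state(anchor, k4, k27), "active")
  # K4me1 alone: poised
  expect_equal(call_enhancer_state(anchor, k4, none), "poised")
  # 290 bp K4me1 fails the 300 bp length floor: none
  short <- data.frame(chrom = "chrA", start = 100L, end = 390L)
  expect_equal(call_enhancer_state(anchor, short, none), "none")
  # marks touching the anchor but overlapping each other by only 5 bp
  k27_far <- data.frame(chrom = "chrA", start = 495L, end = 900L)
  expect_equal(call_enhancer_state(anchor, k4, k27_far), "poised")
})

test_that("state calling is invariant to peak order and abutting splits", {
  anchor <- data.frame(chrom = "chrA", start = 0L, end = 1000L)
  k4_whole <- data.frame(chrom = "chrA", start = 100L, end = 500L)
  # same region fragmented into abutting pieces, shuffled
  k4_split <- data.frame(chrom = "chrA", start = c(300L, 100L),
                         end = c(500L, 300L))
  k27 <- data.frame(chrom = "chrA", start = 400L, end = 800L)
  expect_equal(call_enhancer_state(anchor, k4_whole, k27),
               call_enhancer_state(anchor, k4_split, k27))
  expect_equal(call_enhancer_state(anchor, k4_split[2:1, ], k27), "active")
})

test_that("prepare_interactome keeps only marked enhancer anchors", {
  w <- default_world()
  swap <- seq_len(nrow(w$interactions)) %% 2L == 0L
  it <- w$interactions
  pairs <- data.frame(
    chrom1 = it$chrom,
    start1 = ifelse(swap, it$e_start, it$p_start),
    end1 = ifelse(swap, it$e_end, it$p_end),
    chrom2 = it$chrom,
    start2 = ifelse(swap, it$p_start, it$e_start),
    end2 = ifelse(swap, it$p_end, it$e_end),
    id = it$id, replicate = it$replicate, pet_count = it$pet_count)
  k4 <- w$peaks_source[w$peaks_source$mark == "H3K4me1", ]
  k27 <- w$peaks_source[w$peaks_source$mark == "H3K27Ac", ]
  lri <- prepare_interactome(pairs, w$genes_source, k4, k27)
  expect_equal(nrow(lri), nrow(it))
  expect_equal(lri$enhancer_state[match(it$id, lri$id)], it$enhancer_state)
  # promoter-first normalization recovered the planted orientation
  expect_equal(lri$p_start[match(it$id, lri$id)], it$p_start)
})
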