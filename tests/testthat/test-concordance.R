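# Shuffled nulls, conservation comparison, mark concordance, TAD and loop
# representation, cCRE and validated-enhancer overlap.

test_that("shuffling is seeded, length-preserving and bounded", {
  regions <- data.frame(chrom = c("c1", "c1", "c2"),
                        start = c(0L, 500L, 100L),
                        end = c(100L, 900L, 400L))
  sizes <- c(c1 = 10000L, c2 = 5000L)
  n1 <- shuffle_regions(regions, sizes, seed = 4)
  n2 <- shuffle_regions(regions, sizes, seed = 4)
  expect_identical(n1, n2)
  expect_equal(n1$end - n1$start, regions$end - regions$start)
  expect_equal(n1$chrom, regions$chrom)
  expect_true(all(n1$start >= 0 & n1$end <= sizes[n1$chrom]))
  # forced placement: chromosome exactly as long as the region
  one <- shuffle_regions(data.frame(chrom = "c3", start = 0L, end = 700L),
                         c(c3 = 700L), seed = 1)
  expect_equal(c(one$start, one$end), c(0L, 700L))
  expect_error(
    shuffle_regions(data.frame(chrom = "c3", start = 0L, end = 800L),
                    c(c3 = 700L), seed = 1), "does not fit")
})

test_that("shuffled starts are uniform on their chromosome", {
  regions <- data.frame(chrom = "c1", start = rep(0L, 10000L),
                        end = rep(100L, 10000L))
  null <- shuffle_regions(regions, c(c1 = 10000L), seed = 6)
  bins <- cut(null$start, breaks = seq(0, 9900, length.out = 11),
              include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})

test_that("conservation comparison separates planted signal and flags ties", {
  # planted: regions on 0.9-scoring DNA, null on 0.1 background
  fg <- data.frame(chrom = "c1", start = seq(0L, 99000L, 1000L))
  fg$end <- fg$start + 200L
  fg <- fg[1:100, ]
  track <- rbind(
    data.frame(chrom = "c1", start = c(fg$end),
               end = c(fg$start[-1], 200000L), score = 0.1),
    data.frame(chrom = "c1", start = fg$start, end = fg$end, score = 0.9))
  null <- data.frame(chrom = "c1", start = fg$start + 300L,
                     end = fg$start + 500L)
  res <- conservation_compare(fg, null, track)
  expect_lt(res$p_value, 1e-4)
  expect_equal(mean(res$region_scores), 0.9)
  expect_equal(mean(res$null_scores), 0.1)
  # identical score vectors: degenerate tie, p = 1
  tie <- conservation_compare(fg, fg, track)
  expect_equal(tie$p_value, 1)
  expect_error(conservation_compare(fg[0, ], null, track), "empty")
})

test_that("mark matching uses the 50 bp floor and exact planted rates", {
  # 10 enhancers; layer overlaps 6 of them by >= 50 bp, one by 49 bp
  enh <- data.frame(id = sprintf("e%02d", 1:10), chrom = "c1",
                    start = seq(0L, 90000L, 10000L))
  enh$end <- enh$start + 2000L
  peaks <- data.frame(chrom = "c1",
                      start = c(enh$start[1:6] + 100L, enh$start[7] + 1951L),
                      end = c(enh$start[1:6] + 600L, enh$start[7] + 2300L))
  res <- mark_concordance(enh, list(tissueX = list(H3K4me1 = peaks)))
  tab <- res$table
  expect_equal(sum(tab$matched), 6)
  expect_false(tab$matched[tab$id == "e07"])  # 49 bp overlap
  expect_equal(tab$overlap_bp[tab$id == "e07"], 49)
  expect_equal(res$summary$matched_pct, 60)
  expect_equal(tab$coverage_fraction[tab$id == "e01"], 500 / 2000)
  expect_equal(tab$state_in_human[tab$matched], rep("unknown", 6))
})

test_that("states in the target species need both marks", {
  enh <- data.frame(id = c("a", "b"), chrom = "c1", start = c(0L, 10000L),
                    end = c(2000L, 12000L))
  k4 <- data.frame(chrom = "c1", start = c(100L, 10100L),
                   end = c(700L, 10700L))
  k27 <- data.frame(chrom = "c1", start = 100L, end = 700L)
  res <- mark_concordance(enh, list(t1 = list(H3K4me1 = k4, H3K27Ac = k27)))
  expect_equal(res$table$state_in_human, c("active", "poised"))
})

test_that("cumulative unique counts follow union arithmetic", {
  expect_equal(cumulative_match(list(t1 = c("a", "b", "c")))$cumulative_unique,
               3L)
  two <- cumulative_match(list(t1 = c("a", "b", "c"),
                               t2 = c("d", "e", "f", "g")))
  expect_equal(two$cumulative_unique, c(3L, 7L))
  nested <- cumulative_match(list(big = c("a", "b", "c", "d"),
                                  small = c("a", "b")))
  expect_equal(nested$tissue, c("small", "big"))
  expect_equal(nested$cumulative_unique, c(2L, 4L))
  # non-decreasing and ends at the union size, regardless of tie order
  w <- default_world()
  sets <- w$truth$tissue_matched
  cm <- cumulative_match(sets)
  expect_true(all(diff(cm$cumulative_unique) >= 0))
  expect_equal(cm$cumulative_unique[length(sets)],
               length(unique(unlist(sets))))
})

test_that("TAD status distinguishes intra, inter and outside", {
  hms <- data.frame(
    id = c("r1", "r2", "r3"),
    p_chrom = "c1", p_start = c(10000L, 10000L, 10000L),
    p_end = c(12000L, 12000L, 12000L),
    e_chrom = "c1", e_start = c(30000L, 30000L, 30000L),
    e_end = c(32000L, 32000L, 32000L), stringsAsFactors = FALSE)
  tads <- list(
    one = data.frame(chrom = "c1", start = 0L, end = 1000000L),
    adjacent = data.frame(chrom = "c1", start = c(0L, 20000L),
                          end = c(20000L, 1000000L)),
    gap = data.frame(chrom = "c1", start = 0L, end = 20000L))
  res <- tad_call(hms[1, ], tads)
  st <- setNames(res$table$status, res$table$dataset)
  expect_equal(st[["one"]], "intra")
  expect_equal(st[["adjacent"]], "inter")
  expect_equal(st[["gap"]], "outside")
  expect_equal(res$intra_any, "r1")
  # input order of TADs is irrelevant
  res2 <- tad_call(hms[1, ], lapply(tads, function(d) d[rev(seq_len(nrow(d))), ]))
  expect_equal(res2$table$status, res$table$status)
})

test_that("planted TAD composition is recovered on the world", {
  w <- default_world()
  hms <- map_interactions(w$interactions, w$chains)
  ppe <- hms[hms$synteny_class == "P_plus_E", ]
  res <- tad_call(ppe, w$tad_sets)
  for (ds in names(w$tad_sets)) {
    got <- res$table[res$table$dataset == ds, ]
    expect_equal(setNames(got$status, got$id), w$truth$tad[[ds]])
  }
})

test_that("loop representation is orientation-free and deduplicated", {
  hms <- data.frame(id = c("r1", "r2"), p_chrom = "c1",
                    p_start = c(1000L, 50000L), p_end = c(3000L, 52000L),
                    e_chrom = "c1", e_start = c(20000L, 70000L),
                    e_end = c(22000L, 72000L), stringsAsFactors = FALSE)
  exact <- data.frame(chrom1 = "c1", start1 = 1000L, end1 = 3000L,
                      chrom2 = "c1", start2 = 20000L, end2 = 22000L)
  swapped <- data.frame(chrom1 = "c1", start1 = 20500L, end1 = 21000L,
                        chrom2 = "c1", start2 = 1500L, end2 = 2500L)
  res <- loop_representation(hms, list(d1 = exact, d2 = swapped))
  expect_equal(res$sets$d1, "r1")
  expect_equal(res$sets$d2, "r1")
  expect_equal(res$total_unique, 1L)
  expect_equal(res$total_unique_pct, 50)
})

test_that("planted loop coverage with redundancy gives the union by inclusion-exclusion", {
  cfg <- world_config(n_per_class = c(P_plus_E = 20L, split = 2L,
                                      E_only = 2L, P_only = 2L, lost = 2L),
                      seed = 5)
  w <- build_world(cfg)
  hms <- map_interactions(w$interactions, w$chains)
  ppe <- hms[hms$synteny_class == "P_plus_E", ]
  res <- loop_representation(ppe, w$loop_sets)
  # 30% + 30% coverage with 50% shared: union = 6 + 6 - 3 = 9 of 20 (45%)
  expect_equal(sort(res$summary$represented), c(6L, 6L))
  expect_equal(res$total_unique, 9L)
  expect_equal(res$total_unique_pct, 45)
  for (ds in names(w$loop_sets))
    expect_setequal(res$sets[[ds]], w$truth$loops[[ds]])
})

test_that("cCRE overlap recovers the planted rate and subclass tallies", {
  w <- default_world()
  src_enh <- data.frame(id = w$interactions$id,
                        chrom = w$interactions$e_chrom,
                        start = w$interactions$e_start,
                        end = w$interactions$e_end)
  res <- ccre_overlap(src_enh, w$ccres)
  expect_equal(res$n_overlapping, length(w$truth$ccre_ids))
  expect_setequal(unique(res$table$id), w$truth$ccre_ids)
  expect_equal(res$overlap_pct,
               pct(length(w$truth$ccre_ids), nrow(src_enh)))
  expect_true(all(res$per_subclass$fraction <= 1))
  # no cCREs: all zero
  empty <- ccre_overlap(src_enh, w$ccres[0, ])
  expect_equal(empty$overlap_pct, 0)
})

test_that("validated-enhancer positives and negatives are reported separately", {
  w <- default_world()
  hms <- map_interactions(w$interactions, w$chains)
  ppe <- hms[hms$synteny_class == "P_plus_E", ]
  enh <- data.frame(id = ppe$id, chrom = ppe$e_chrom, start = ppe$e_start,
                    end = ppe$e_end)
  res <- vista_overlap(enh, w$vista)
  expect_equal(res$n_positive_elements, w$config$vista_pos_in)
  expect_equal(nrow(res$negative), 0)
  # a 1 bp touch counts
  touch <- data.frame(chrom = enh$chrom[1], start = enh$end[1] - 1L,
                      end = enh$end[1] + 500L, element_id = "VP_X",
                      label = "positive")
  expect_equal(nrow(vista_overlap(enh, touch)$positive), 1)
})
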