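# Generator invariants: planted truth, chain consistency, bounds,
# reproducibility, and the planted CNV cohorts.

test_that("every planted class is legal and intervals sit inside bounds", {
  w <- default_world()
  expect_true(all(w$interactions$truth_class %in%
                    c("P_plus_E", "split", "E_only", "P_only", "lost")))
  it <- w$interactions
  expect_true(all(it$p_start >= 0 & it$e_start >= 0))
  expect_true(all(it$p_end <= w$source_chrom_sizes[it$chrom]))
  expect_true(all(it$e_end <= w$source_chrom_sizes[it$e_chrom]))
  mapped <- !is.na(it$t_e_chrom)
  expect_true(all(it$t_e_end[mapped] <=
                    w$target_chrom_sizes[it$t_e_chrom[mapped]]))
  # chain arithmetic is internally consistent (validate_chain errors if not)
  for (ch in w$chains) expect_silent(validate_chain(ch))
})

test_that("a verbatim-copied chromosome lifts over as the identity", {
  w <- build_world(world_config(identity_chrom = TRUE))
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(0:99000, 1); b <- a + sample(1:900, 1)
    r <- map_interval("mchrI", a, b, w$chains)
    expect_equal(r$status, "mapped")
    expect_equal(c(r$t_chrom, r$t_start, r$t_end),
                 c("hchrI", a, b))
    expect_equal(r$mapped_fraction, 1)
  }
})

test_that("round trip through the emitted chain and its inverse is the identity", {
  w <- default_world()
  inv <- lapply(w$chains, invert_chain)
  it <- w$interactions
  ppe <- it[it$truth_class == "P_plus_E", ]
  for (i in seq_len(nrow(ppe))) {
    fwd <- map_interval(ppe$e_chrom[i], ppe$e_start[i], ppe$e_end[i],
                        w$chains)
    expect_equal(fwd$status, "mapped")
    back <- map_interval(fwd$t_chrom, fwd$t_start, fwd$t_end, inv)
    expect_equal(back$status, "mapped")
    expect_equal(c(back$t_chrom, back$t_start, back$t_end),
                 c(ppe$e_chrom[i], ppe$e_start[i], ppe$e_end[i]))
  }
})

test_that("a 40%-preserved anchor is counted base-exactly by the oracle", {
  w <- default_world()
  it <- w$interactions
  ponly <- it[it$truth_class == "P_only", ][1, ]
  o <- oracle_map_interval(ponly$e_chrom, ponly$e_start, ponly$e_end,
                           w$chains)
  expect_equal(o$mapped_fraction, 0.4)
  expect_equal(o$status, "unmapped")
  # and the promoter of the same interaction is fully preserved
  op <- oracle_map_interval(ponly$chrom, ponly$p_start, ponly$p_end,
                            w$chains)
  expect_equal(op$mapped_fraction, 1)
})

test_that("the same seed reproduces the world; different seeds differ", {
  w1 <- build_world(world_config(seed = 77))
  w2 <- build_world(world_config(seed = 77))
  w3 <- build_world(world_config(seed = 78))
  expect_identical(w1$interactions, w2$interactions)
  expect_identical(w1$cnv_case, w2$cnv_case)
  expect_false(identical(w1$cnv_case$start, w3$cnv_case$start))
})

test_that("infeasible configurations fail naming the constraint", {
  expect_error(world_config(partial_keep_frac = 0.6), "partial_keep_frac")
  expect_error(world_config(anchor_len = 50), "anchor_len")
  expect_error(world_config(anchor_len = 25000), "infeasible")
  expect_error(
    build_world(world_config(n_per_class = c(P_plus_E = 0L, split = 0L,
                                             E_only = 0L, P_only = 0L,
                                             lost = 0L))),
    "no interactions")
})

test_that("planted CNV cohorts record marginals equal to the cohort sizes", {
  w <- default_world()
  expect_equal(unname(colSums(w$cnv_table)),
               c(w$config$cnv$n_case, w$config$cnv$n_control))
  expect_equal(nrow(w$cnv_case), w$config$cnv$n_case)
  # planted flags agree with realized geometry: every planted hit overlaps
  # some interaction anchor, no planted miss does
  ppe <- w$interactions[w$interactions$truth_class == "P_plus_E", ]
  regions <- rbind(
    data.frame(chrom = ppe$t_e_chrom, start = ppe$t_e_start,
               end = ppe$t_e_end),
    data.frame(chrom = ppe$t_p_chrom, start = ppe$t_p_start,
               end = ppe$t_p_end))
  for (cohort in list(w$cnv_case, w$cnv_control)) {
    hit <- syntenicLRI:::.overlaps_any(
      cohort[, c("chrom", "start", "end")], regions)
    expect_equal(hit, cohort$planted_hit)
  }
})

test_that("re-planting at odds ratio 1 equalizes the cohort hit rates", {
  w <- plant_cnv_enrichment(default_world(), odds_ratio = 1,
                            n_case = 2000L, n_control = 2000L, seed = 9L)
  rates <- colSums(w$cnv_table[1, , drop = FALSE]) / colSums(w$cnv_table)
  expect_lt(abs(rates[["case"]] - rates[["control"]]), 0.05)
})
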