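test_that("per-cytosine extraction counts calls by position, strand and state", {
  aln <- make_aln(c("Z", "Z", "z"), start = 5L)
  pc <- extract_per_cytosine(aln)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$meth_count, 2L)
  expect_equal(pc$total_count, 3L)
  expect_equal(pc$percent, 100 * 2 / 3)
  expect_equal(pc$context, "CG")
  expect_equal(pc$strand, "+")

  empty <- extract_per_cytosine(make_aln(character(0)))
  expect_equal(nrow(empty), 0L)

  # OB reads observe the bottom strand at the same coordinates
  both <- bs_alignments(rbind(make_aln("Z", start = 3L, bs_strand = "OT"),
                              make_aln("z", start = 3L, bs_strand = "OB",
                                       read_id = "r2")))
  pc2 <- extract_per_cytosine(both)
  expect_equal(pc2$strand, c("+", "-"))
  expect_equal(pc2$percent, c(100, 0))

  # duplicates skipped by default
  dup <- make_aln(c("Z", "Z"), start = 1L, is_duplicate = c(FALSE, TRUE))
  expect_equal(extract_per_cytosine(dup)$total_count, 1L)
  expect_equal(extract_per_cytosine(dup, include_duplicates = TRUE)$total_count, 2L)
})

test_that("extraction recovers the simulated truth within binomial error", {
  g <- synth_genome(5000, seed = 71)
  sim <- simulate_wgbs(g, methylome_model(p_mCG = 0.4), protocol_model(),
                       depth = 40, seed = 72)
  pc <- extract_per_cytosine(sim$alignments, contexts = "CG")
  tru <- as.data.frame(sim$truth$positions)
  tru <- tru[tru$context == "CG", ]
  m <- merge(pc, tru, by = c("chrom", "pos", "strand"))
  expect_gt(nrow(m), 400)
  # global agreement: the measurement samples the same molecules
  expect_lt(abs(global_methylation(pc) -
                  sim$truth$global$true_percent[sim$truth$global$context == "CG"]),
            3 * 100 * sqrt(0.25 / sum(pc$total_count)))
  # per-position: deviations scale with per-position coverage
  z <- (m$percent - m$true_percent) /
    (100 * sqrt(pmax(m$true_percent / 100 * (1 - m$true_percent / 100), 0.002) /
                  m$total_count))
  expect_lt(mean(abs(z) > 4), 0.01)
})

test_that("region methylation: pooled vs per-cytosine mean arithmetic", {
  pc <- data.frame(chrom = "c", pos = c(5L, 9L), strand = "+", context = "CG",
                   meth_count = c(9L, 0L), total_count = c(10L, 1L),
                   percent = c(90, 0))
  reg <- genomic_intervals("c", 0L, 20L)
  expect_equal(region_methylation(pc, reg, "pooled")$value, 100 * 9 / 11)
  expect_equal(region_methylation(pc, reg, "cytosine_mean")$value, 45)

  single <- pc[1, ]
  expect_equal(region_methylation(single, reg, "pooled")$value,
               region_methylation(single, reg, "cytosine_mean")$value)

  # strategies agree exactly under equal coverage
  eq <- transform(pc, total_count = 10L, meth_count = c(9L, 0L),
                  percent = c(90, 0))
  expect_equal(region_methylation(eq, reg, "pooled")$value,
               region_methylation(eq, reg, "cytosine_mean")$value)

  # minimum observation rule
  few <- region_methylation(pc[2, ], reg, "pooled", min_region_obs = 3)
  expect_false(few$included)
  expect_true(is.na(few$value))
})

test_that("global methylation is the coverage-weighted mean of percents", {
  set.seed(73)
  pc <- data.frame(chrom = "c", pos = 1:50, strand = "+", context = "CG",
                   total_count = sample(1:30, 50, TRUE))
  pc$meth_count <- rbinom(50, pc$total_count, 0.3)
  pc$percent <- 100 * pc$meth_count / pc$total_count
  expect_equal(global_methylation(pc),
               weighted.mean(pc$percent, pc$total_count))
  all_m <- transform(pc, meth_count = total_count, percent = 100)
  expect_equal(global_methylation(all_m), 100)
  expect_warning(v <- global_methylation(pc[0, ]), "undefined")
  expect_true(is.na(v))
})

test_that("fixed-cytosine-count tiles follow the greedy partition with remainder discard", {
  g <- ref_genome(c(c1 = strrep("CGAT", 3)))  # CG cytosines at 0,4,8 (+) and 1,5,9 (-)
  t3 <- cytosine_tiles(g, 3)
  expect_equal(nrow(t3), 2L)
  expect_equal(attr(t3, "n_discarded_positions"), 0L)

  g2 <- ref_genome(c(c1 = paste(rep("CGTT", 7), collapse = "")))  # 14 CG cytosines
  t4 <- cytosine_tiles(g2, 4)
  expect_equal(nrow(t4), 3L)
  expect_equal(attr(t4, "n_discarded_positions"), 2L)

  set.seed(74)
  g3 <- synth_genome(3000, seed = 74)
  for (n in c(3, 10, 25)) {
    got <- cytosine_tiles(g3, n)
    ct <- cytosine_context_table(g3)
    want <- oracle_tile_bounds(ct$pos[ct$context == "CG"], n)
    expect_equal(unname(cbind(got$start, got$end)), unname(want))
  }
})

test_that("differential tiles: strict threshold, antisymmetry, self-comparison", {
  tiles <- genomic_intervals("c", c(0L, 100L, 200L), c(50L, 150L, 250L))
  va <- tiles; va$value <- c(10, 50, NA); va$included <- !is.na(va$value)
  vb <- tiles; vb$value <- c(35, 60, 80); vb$included <- TRUE
  d <- differential_regions(va, vb, 20)
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "b_gt_a")
  expect_equal(d$start, 0L)

  # exactly 20 is not selected (strictly greater than)
  vb2 <- vb; vb2$value <- c(30, 60, 80)
  expect_equal(nrow(differential_regions(va, vb2, 20)), 0L)

  swapped <- differential_regions(vb, va, 20)
  expect_equal(swapped$direction, "a_gt_b")
  expect_equal(swapped[c("chrom", "start", "end")], d[c("chrom", "start", "end")])

  expect_equal(nrow(differential_regions(va, va, 20)), 0L)
  expect_error(differential_regions(va, vb[1:2, ]), "tile frame")
})

test_that("overlap counting is by tile identity", {
  t1 <- genomic_intervals("c", c(0L, 100L), c(50L, 150L))
  t2 <- genomic_intervals("c", c(100L, 200L), c(150L, 250L))
  expect_equal(overlap_count(t1, t2), list(a_only = 1L, shared = 1L, b_only = 1L))
  expect_equal(overlap_count(t1, t1), list(a_only = 0L, shared = 2L, b_only = 0L))
  t3 <- genomic_intervals("c", 300L, 350L)
  expect_equal(overlap_count(t1, t3)$shared, 0L)
})

test_that("position profiles sign the bottom strand negative", {
  top <- make_aln(c("H", "H", "h", "h", "h", "h", "h", "h", "h", "h"),
                  start = 3L, bs_strand = "OT")
  bot <- make_aln(c("H", "H", "h", "h", "h", "h", "h", "h", "h", "h"),
                  start = 7L, bs_strand = "OB",
                  read_id = paste0("q", 1:10))
  prof <- per_position_profile(bs_alignments(rbind(top, bot)))
  expect_equal(prof$signed_percent[prof$strand == "+"], 20)
  expect_equal(prof$signed_percent[prof$strand == "-"], -20)
  expect_error(per_position_profile(make_aln(c("H", "H"), chrom = c("a", "b"))),
               "single reference")
})
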