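test_that("strand read counts assign by bisulfite-strand provenance", {
  aln <- make_aln(rep("....", 4), chrom = "sat",
                  bs_strand = c("OT", "OT", "CTOT", "OB"))
  sc <- strand_read_counts(aln, "sat")
  expect_equal(sc$top_count, 3L)
  expect_equal(sc$bottom_count, 1L)
  expect_equal(sc$top_proportion, 0.75)
  expect_equal(sc$top_count + sc$bottom_count, nrow(aln))
  empty <- strand_read_counts(aln[0, ], "sat")
  expect_true(is.na(empty$top_proportion))
})

test_that("balanced null simulation gives ~50:50 strands; degradation skews to the C-poor strand", {
  sk <- skewed_reference(10000, c_top = 0.12, g_top = 0.24, seed = 61)
  null <- simulate_wgbs(sk, methylome_model(), protocol_model(), depth = 20, seed = 62)
  p0 <- strand_read_counts(null$alignments)$top_proportion
  n0 <- nrow(null$alignments)
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / n0))

  beta <- calibrate_breakage(2, 0.15, 150)
  deg <- simulate_wgbs(sk, methylome_model(), protocol_model(beta_unmod = beta),
                       depth = 20, seed = 62)
  expect_gt(strand_read_counts(deg$alignments)$top_proportion, 0.5)
})

test_that("tandem unit counting is non-overlapping and matches the scan oracle", {
  expect_equal(unname(tandem_unit_histogram(
    c(r = strrep("TTAGGG", 3)), "TTAGGG")$counts["3"]), 1L)
  expect_equal(unname(tandem_unit_histogram(
    c(r = "TTTTAATTTTAA"), "TTAGGG")$counts["0"]), 1L)
  # reversed orientation scans the reverse complement (PBAT-type libraries)
  h <- tandem_unit_histogram(c(r = strrep("CCCTAA", 4)), "TTAGGG",
                             orientation = "reversed")
  expect_equal(h$motif, "CCCTAA")
  expect_equal(unname(h$counts["4"]), 1L)

  set.seed(63)
  reads <- replicate(300, random_seq(sample(30:90, 1)))
  names(reads) <- paste0("r", seq_along(reads))
  for (motif in c("TTAGGG", "TTTTAA", "AA")) {
    got <- tandem_unit_histogram(reads, motif)
    want <- vapply(reads, oracle_tandem_count, 0L, motif = motif)
    wtab <- table(factor(want, levels = 0:max(want)))
    expect_equal(as.integer(got$counts), as.integer(wtab))
  }
})

test_that("reads seeded with known unit counts reproduce the histogram", {
  set.seed(64)
  units <- sample(0:8, 200, replace = TRUE)
  reads <- vapply(units, function(u)
    paste0(random_seq(5, c("A", "C", "T")), strrep("TTAGGG", u),
           random_seq(5, c("A", "C", "T"))), "")
  names(reads) <- paste0("r", seq_along(reads))
  h <- tandem_unit_histogram(reads, "TTAGGG")
  expect_equal(as.integer(h$counts), as.integer(table(factor(units, levels = 0:8))))
})

test_that("min-units filtering drops low bins and is idempotent", {
  h <- structure(list(motif = "TTAGGG", orientation = "as_given",
                      counts = c(`1` = 10L, `4` = 5L, `5` = 2L, `8` = 1L),
                      min_units_applied = 0L), class = "tandem_histogram")
  f <- filter_min_units(h, 5)
  expect_equal(f$counts, c(`5` = 2L, `8` = 1L))
  expect_equal(f$min_units_applied, 5L)
  expect_equal(filter_min_units(f, 5)$counts, f$counts)
  expect_equal(filter_min_units(h, 0)$counts, h$counts)
})

test_that("high-coverage mask uses a strict threshold on reads per window", {
  g <- ref_genome(c(c1 = strrep("A", 3000)))
  mk <- function(n, at) make_aln(rep(".....", n), start = at,
                                 read_id = paste0("r", seq_len(n), "_", at),
                                 chrom = "c1")
  aln <- bs_alignments(rbind(mk(1001, 10L), mk(1000, 1500L)))
  mask <- high_coverage_mask(aln, g, window = 1000, max_reads = 1000)
  expect_equal(nrow(mask), 1L)
  expect_equal(mask$start, 0L)
  expect_equal(mask$end, 1000L)
  expect_equal(nrow(high_coverage_mask(aln[0, ], g)), 0L)
  kept <- apply_mask(aln, mask)
  expect_true(all(kept$start >= 1000L))
})

test_that("per-tile G/C percentages match a brute-force tally; profile is order-invariant", {
  set.seed(66)
  g <- ref_genome(c(c1 = random_seq(3000), c2 = random_seq(1234)))
  starts <- c(sample.int(2900, 150) - 1L, sample.int(1100, 80) - 1L)
  chroms <- rep(c("c1", "c2"), c(150, 80))
  aln <- make_aln(strrep(".", 100), start = starts, chrom = chroms,
                  read_id = paste0("r", seq_along(starts)))
  prof <- tile_gc_coverage(aln, g, tile = 100, axis = "G")
  for (i in sample(nrow(prof$tiles), 20)) {
    t <- prof$tiles[i, ]
    sub <- substring(g[[t$chrom]], t$start + 1, t$end)
    expect_equal(t$pct, 100 * sum(strsplit(sub, "")[[1]] == "G") / (t$end - t$start))
  }
  expect_equal(sum(prof$profile$tile_count), nrow(prof$tiles))
  shuf <- aln[sample(nrow(aln)), ]
  prof2 <- tile_gc_coverage(bs_alignments(shuf), g, tile = 100, axis = "G")
  expect_equal(prof2$profile, prof$profile)
  # normalised counts total 1 when every read midpoint lands in a tile
  expect_equal(sum(prof$tiles$norm_count), 1)
})

test_that("masked tiles are excluded from the GC profile background", {
  g <- ref_genome(c(c1 = strrep("ACGT", 500)))
  aln <- make_aln(strrep(".", 50), start = rep(c(10L, 900L), c(30, 5)),
                  read_id = paste0("r", 1:35), chrom = "c1")
  mask <- genomic_intervals("c1", 0L, 100L)
  prof <- tile_gc_coverage(aln, g, tile = 100, mask = mask)
  expect_equal(sum(prof$profile$tile_count), 19L)  # 20 tiles minus 1 masked
  expect_equal(prof$total_reads, 5L)               # reads in the mask dropped
})

test_that("uniform coverage yields a flat GC profile and flat feature trend", {
  set.seed(67)
  g <- ref_genome(c(c1 = random_seq(4000)))
  aln <- make_aln(strrep(".", 40), start = seq(0L, 3960L, by = 8L),
                  read_id = paste0("r", 1:496), chrom = "c1")
  prof <- tile_gc_coverage(aln, g, tile = 100)
  mn <- prof$profile$mean_norm_count
  # evenly spaced reads: interior tiles differ by at most one midpoint and
  # the two edge tiles by a few (footprint midpoints cannot reach the ends)
  expect_lt(diff(range(mn[!is.na(mn)])), 3.5 / 496)

  feats <- genomic_intervals("c1", c(1000L, 2500L), c(1400L, 2900L))
  tr <- feature_relative_coverage(aln, feats, g, flank = 300, body_bins = 8,
                                  flank_bins = 3)
  expect_true(all(abs(tr$rel_coverage - 1) < 0.15))
})

test_that("reads placed only inside features raise body bins above flanks", {
  g <- ref_genome(c(c1 = strrep("ACGT", 2500)))
  feats <- genomic_intervals("c1", c(2000L, 6000L), c(3000L, 7000L))
  starts <- c(seq(2000L, 2950L, by = 10L), seq(6000L, 6950L, by = 10L))
  aln <- make_aln(strrep(".", 50), start = starts,
                  read_id = paste0("r", seq_along(starts)), chrom = "c1")
  tr <- feature_relative_coverage(aln, feats, g, flank = 500, body_bins = 6,
                                  flank_bins = 2)
  expect_true(all(tr$rel_coverage[tr$zone == "body"] > 1))
  expect_true(all(tr$rel_coverage[tr$zone != "body"] < 1))
})

test_that("minus-strand features are flipped in the trend", {
  g <- ref_genome(c(c1 = strrep("A", 2000)))
  feats <- genomic_intervals("c1", 500L, 1000L, strand = "-")
  aln <- make_aln(strrep(".", 20), start = seq(500L, 740L, by = 10L),
                  read_id = paste0("r", 1:25), chrom = "c1")
  tr <- feature_relative_coverage(aln, feats, g, flank = 200, body_bins = 4,
                                  flank_bins = 2)
  body <- tr$rel_coverage[tr$zone == "body"]
  # coverage sits at the feature start (left), which after flipping is the
  # profile's right end
  expect_gt(body[4], body[1])
})
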