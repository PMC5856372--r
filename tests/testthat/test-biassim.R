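test_that("fragment counts, bounds and determinism", {
  g <- synth_genome(10000, seed = 81)
  fr <- fragment_genome(g, 150, 15, depth = 10, seed = 82)
  expect_equal(nrow(fr), round(10 * 10000 / 150))
  expect_true(all(fr$start >= 0 & fr$end <= 10000 & fr$start < fr$end))
  fr2 <- fragment_genome(g, 150, 15, depth = 10, seed = 82)
  expect_identical(as.data.frame(fr), as.data.frame(fr2))
  fr3 <- fragment_genome(g, 150, 15, depth = 10, seed = 83)
  expect_false(identical(fr$start, fr3$start))
  short <- ref_genome(c(tiny = strrep("ACGT", 10)))
  expect_warning(fw <- fragment_genome(short, 150, 15, depth = 5, seed = 84),
                 "whole-molecule")
  expect_true(all(fw$end - fw$start == 40))
})

test_that("fragment length and start distributions match the model", {
  g <- synth_genome(50000, seed = 85)
  fr <- fragment_genome(g, 120, 12, depth = 24, seed = 86)  # 10,000 fragments
  len <- fr$end - fr$start
  expect_lt(abs(mean(len) - 120), 1)
  expect_lt(abs(sd(len) - 12), 1)
  # jitter inside the 1-bp grid to break integer ties for the KS statistic
  u <- (fr$start + stats::runif(nrow(fr))) / (50000 - len + 1)
  expect_gt(stats::ks.test(u, "punif")$p.value, 1e-4)
  expect_lt(abs(mean(fr$strand == "+") - 0.5), 0.02)
})

test_that("methylome assignment: deterministic extremes and binomial mid-range", {
  g <- synth_genome(3000, seed = 87)
  fr <- fragment_genome(g, 150, 10, depth = 10, seed = 88)
  all1 <- apply_methylome(fr, g, methylome_model(p_mCG = 1), seed = 89)
  cg <- all1$states[all1$states$context == "CG", ]
  expect_true(all(cg$modified))
  expect_true(!any(all1$states$modified[all1$states$context != "CG"]))
  all0 <- apply_methylome(fr, g, methylome_model(), seed = 89)
  expect_true(!any(all0$states$modified))
  half <- apply_methylome(fr, g, methylome_model(p_mCG = 0.5), seed = 90)
  hcg <- half$states[half$states$context == "CG", ]
  expect_gt(nrow(hcg), 1200)
  expect_lt(abs(mean(hcg$modified) - 0.5), 3 * sqrt(0.25 / nrow(hcg)))
})

test_that("survival follows the closed form and the null protocol converts fully", {
  # fragments engineered with exactly 10 unmodified cytosines
  g <- ref_genome(c(frag = paste0(strrep("CAAT", 10), strrep("AT", 30))))
  n <- 4000L
  fr <- data.table::data.table(frag_id = seq_len(n), chrom = "frag",
                               start = 0L, end = 100L, strand = "+")
  mol <- apply_methylome(fr, g, methylome_model(), seed = 91)
  beta <- 1 - 0.5^(1 / 10)
  conv <- bisulfite_convert(mol, protocol_model(beta_unmod = beta), g, seed = 92)
  s <- mean(conv$fragments$survived)
  expect_lt(abs(s - 0.5), 3 * sqrt(0.25 / n))

  conv0 <- bisulfite_convert(mol, protocol_model(), g, seed = 93)
  expect_true(all(conv0$fragments$survived))
  expect_true(all(conv0$states$meth_call == FALSE))
})

test_that("modification protects against degradation; survival is monotone in beta", {
  g <- synth_genome(4000, gc = 0.6, cpg_factor = 1, seed = 94)
  fr <- fragment_genome(g, 150, 10, depth = 20, seed = 95)
  surv_at <- function(p_m, beta) {
    mol <- apply_methylome(fr, g, methylome_model(p_mCG = p_m, p_mCH = p_m),
                           seed = 96)
    conv <- bisulfite_convert(mol, protocol_model(beta_unmod = beta), g, seed = 97)
    mean(conv$fragments$survived)
  }
  expect_gt(surv_at(1, 0.02), surv_at(0, 0.02))
  expect_gt(surv_at(0, 0.01), surv_at(0, 0.04))
})

test_that("PCR closed forms and monotone G enrichment", {
  g <- synth_genome(20000, seed = 98)
  fr <- fragment_genome(g, 150, 15, depth = 5, seed = 99)
  mol <- apply_methylome(fr, g, methylome_model(), seed = 100)
  conv <- bisulfite_convert(mol, protocol_model(), g, seed = 101)

  id <- pcr_amplify(conv, pcr_model(cycles = 0), g, seed = 102)
  expect_true(all(id$fragments$copies == conv$fragments$copies))

  x8 <- pcr_amplify(conv, pcr_model(cycles = 3, efficiency_base = 1), g, seed = 103)
  expect_true(all(x8$fragments$copies[x8$fragments$survived] == 8))

  gmean <- vapply(c(0L, 3L, 6L), function(cyc) {
    a <- pcr_amplify(conv, pcr_model(cycles = cyc, efficiency_slope = 2), g,
                     seed = 104)
    fa <- a$fragments[a$fragments$copies > 0, ]
    weighted.mean(fa$g_frac, fa$copies)
  }, 0)
  expect_true(all(diff(gmean) > 0))
})

test_that("read emission: call strings reflect the per-molecule truth exactly", {
  g <- ref_genome(c(r = "TTACGTTTTTTTTTACGTT"))
  fr <- data.table::data.table(frag_id = 1:2, chrom = "r", start = 0L,
                               end = 19L, strand = c("+", "-"))
  mol <- apply_methylome(fr, g, methylome_model(p_mCG = 1), seed = 105)
  conv <- bisulfite_convert(mol, protocol_model(), g, seed = 106)
  rd <- emit_reads(conv, g, read_length = 19L)
  aln <- rd$alignments
  expect_equal(aln$call_string[aln$bs_strand == "OT"], "...Z...........Z...")
  expect_equal(aln$call_string[aln$bs_strand == "OB"], "....Z...........Z..")
  expect_equal(unname(rd$raw_reads[aln$bs_strand == "OT"]), "TTACGTTTTTTTTTACGTT")
  # bottom read is reverse complemented into read orientation
  expect_equal(unname(rd$raw_reads[aln$bs_strand == "OB"]),
               wgbsbias:::revcomp("TTACGTTTTTTTTTACGTT"))

  # unmodified molecules convert fully: no uppercase calls, C -> T in raw
  mol0 <- apply_methylome(fr, g, methylome_model(), seed = 107)
  conv0 <- bisulfite_convert(mol0, protocol_model(), g, seed = 108)
  rd0 <- emit_reads(conv0, g, read_length = 19L)
  expect_false(any(grepl("[ZXHU]", rd0$alignments$call_string)))
  expect_equal(unname(rd0$raw_reads[rd0$alignments$bs_strand == "OT"]),
               gsub("C", "T", "TTACGTTTTTTTTTACGTT"))
})

test_that("end-to-end identity: extraction reproduces truth at deterministic rates", {
  g <- synth_genome(3000, seed = 109)
  mm <- blocky_methylome(g, levels = c(0, 1), block_sites = 5)
  sim <- simulate_wgbs(g, mm, protocol_model(), depth = 15, seed = 110)
  pc <- extract_per_cytosine(sim$alignments, contexts = c("CG", "CHG", "CHH"))
  tru <- as.data.frame(sim$truth$positions)
  m <- merge(pc, tru, by = c("chrom", "pos", "strand"))
  expect_equal(m$percent, m$true_percent)
})

test_that("every emitted read traces back to exactly one fragment record", {
  g <- synth_genome(4000, seed = 111)
  sim <- simulate_wgbs(g, methylome_model(p_mCG = 0.5),
                       protocol_model(beta_unmod = 0.01), pcr_model(cycles = 3),
                       depth = 10, seed = 112)
  ids <- as.integer(sub("_c[0-9]+$", "", sub("^frag", "", sim$alignments$read_id)))
  expect_true(all(ids %in% sim$truth$fragments$frag_id[sim$truth$fragments$survived]))
  # copy counts reconcile with the emitted multiset
  tab <- table(ids)
  expect_equal(nrow(sim$alignments), sum(tab))
})

test_that("simulation is byte-reproducible for a fixed seed and differs across seeds", {
  g <- synth_genome(3000, seed = 113)
  s1 <- simulate_wgbs(g, methylome_model(p_mCG = 0.5),
                      protocol_model(beta_unmod = 0.01, epsilon_CH = 0.01),
                      pcr_model(cycles = 2), depth = 8, seed = 7)
  s2 <- simulate_wgbs(g, methylome_model(p_mCG = 0.5),
                      protocol_model(beta_unmod = 0.01, epsilon_CH = 0.01),
                      pcr_model(cycles = 2), depth = 8, seed = 7)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$raw_reads, s2$raw_reads)
  s3 <- simulate_wgbs(g, methylome_model(p_mCG = 0.5),
                      protocol_model(beta_unmod = 0.01, epsilon_CH = 0.01),
                      pcr_model(cycles = 2), depth = 8, seed = 8)
  expect_false(identical(s1$alignments$call_string, s3$alignments$call_string))

  td <- withr::local_tempdir()
  write_simulation(s1, file.path(td, "a"))
  write_simulation(s2, file.path(td, "b"))
  for (f in list.files(file.path(td, "a")))
    expect_identical(readLines(file.path(td, "a", f)),
                     readLines(file.path(td, "b", f)))
})

test_that("overestimation law: degradation inflates measured mCG, protection removes it", {
  g <- synth_genome(30000, seed = 114)
  mm <- methylome_model(p_mCG = 0.5)
  run <- function(beta_u, beta_m) {
    sim <- simulate_wgbs(g, mm, protocol_model(beta_unmod = beta_u,
                                               beta_mod = beta_m),
                         depth = 25, seed = 115)
    global_methylation(extract_per_cytosine(sim$alignments)) -
      sim$truth$global$true_percent[sim$truth$global$context == "CG"]
  }
  expect_gt(run(0.03, 0), 0.3)          # beta_unmod > beta_mod: overestimation
  expect_lt(abs(run(0.03, 0.03)), 0.3)  # equal breakage: no methylation bias
})

test_that("heat-like and alkaline-like presets recover the fourfold conversion contrast", {
  spk <- synth_genome(100000, gc = 0.45, name = "spike", seed = 116)
  eff <- vapply(c("heat_like", "alkaline_like"), function(nm) {
    pr <- sim_preset(nm)$protocol
    sim <- simulate_wgbs(spk, methylome_model(), pr, pcr_model(), depth = 30,
                         seed = 117)
    spike_in_conversion(sim$alignments, "spike")$efficiency
  }, 0)
  expect_gt(eff[["heat_like"]], eff[["alkaline_like"]])
  ratio <- (1 - eff[["alkaline_like"]]) / (1 - eff[["heat_like"]])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 5.5)
})

test_that("amplification-free runs estimate global mCG closer to truth than amplified ones", {
  g <- synth_genome(50000, seed = 118)
  pp <- sim_preset("pbat_like"); hh <- sim_preset("heat_like")
  errs <- vapply(1:3, function(k) {
    e <- function(p) {
      sim <- simulate_wgbs(g, methylome_model(p_mCG = 0.5), p$protocol, p$pcr,
                           depth = 25, seed = 118 + k)
      abs(global_methylation(extract_per_cytosine(sim$alignments)) -
            sim$truth$global$true_percent[sim$truth$global$context == "CG"])
    }
    c(pbat = e(pp), amplified = e(hh))
  }, c(pbat = 0, amplified = 0))
  expect_lt(mean(errs["pbat", ]), mean(errs["amplified", ]))
})
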