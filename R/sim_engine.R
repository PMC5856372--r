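# Generative model of WGBS library preparation. The pipeline mirrors the
# bench protocol: fragment -> assign per-molecule methylation states ->
# bisulfite convert (with degradation) -> PCR amplify -> sequence reads.
# Every stage records its ground truth so diagnostics can be validated by
# parameter recovery.

#' Fragment a genome
#'
#' Draws single-molecule fragments with uniform random start, truncated
#' normal length and equiprobable strand of origin; the fragment count is
#' set to reach the target haploid depth. Each fragment is one
#' single-stranded molecule after denaturation (per-strand independence; no
#' reannealing is modelled).
#'
#' @param genome a [ref_genome()].
#' @param mean_length,length_sd fragment length distribution (bases).
#' @param depth target depth in fragment-bases per genome base.
#' @param seed RNG seed.
#' @return data.table of class `sim_fragments`: `frag_id`, `chrom`,
#'   `start`, `end`, `strand` (`+` = top-strand molecule).
#' @export
fragment_genome <- function(genome, mean_length = 150L, length_sd = 20L,
                            depth = 10, seed = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  lens <- nchar(unclass(genome))
  if (any(lens < mean_length))
    warning("sequence(s) shorter than mean_length: emitted as whole-molecule fragments")
  with_seed(seed, {
    n <- max(1L, round(depth * sum(lens) / mean_length))
    chrom <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
    flen <- pmax(20L, round(stats::rnorm(n, mean_length, length_sd)))
    L <- lens[chrom]
    flen <- pmin(flen, L)
    start <- floor(stats::runif(n, 0, L - flen + 1))
    dt <- data.table::data.table(
      frag_id = seq_len(n), chrom = chrom,
      start = as.integer(start), end = as.integer(start + flen),
      strand = sample(c("+", "-"), n, replace = TRUE))
    data.table::setattr(dt, "class", c("sim_fragments", class(dt)))
    dt
  })
}

#' Assign per-molecule cytosine states
#'
#' For every cytosine on each fragment's strand of origin, draws (or
#' copies) the molecule-level modification state from the methylome model.
#' Probabilistic sites are drawn independently per molecule, so two
#' fragments over the same site can differ.
#'
#' @param fragments a [fragment_genome()] table.
#' @param genome the [ref_genome()] the fragments came from.
#' @param methylome a [methylome_model()].
#' @param seed RNG seed.
#' @return object of class `sim_molecules`: list with `fragments`, `states`
#'   (frag_id, chrom, pos, strand, context, modified, hydroxy) and
#'   `site_index` (the genome's cytosine table with assigned
#'   probabilities).
#' @export
apply_methylome <- function(fragments, genome, methylome, seed = NULL) {
  ct <- cytosine_context_table(genome)
  ct[, p := ifelse(context == "CG", methylome$p_mCG, methylome$p_mCH)]
  if (!is.null(methylome$site_probs)) {
    sp <- data.table::as.data.table(methylome$site_probs)
    ct[sp, p := i.p, on = c("chrom", "pos", "strand")]
  }
  ct[, site_id := .I]
  fr <- data.table::as.data.table(fragments)
  pieces <- vector("list", 0)
  for (grp in split(seq_len(nrow(fr)), paste(fr$chrom, fr$strand))) {
    ch <- fr$chrom[grp[1]]; st <- fr$strand[grp[1]]
    sites <- ct[chrom == ch & strand == st]
    if (nrow(sites) == 0) next
    pos <- sites$pos
    lo <- findInterval(fr$start[grp] - 0.5, pos) + 1L
    hi <- findInterval(fr$end[grp] - 0.5, pos)
    n <- pmax(hi - lo + 1L, 0L)
    has <- n > 0L
    if (!any(has)) next
    idx <- sequence(n[has], from = lo[has])
    pieces[[length(pieces) + 1L]] <- data.table::data.table(
      frag_id = rep(fr$frag_id[grp][has], n[has]),
      site_id = sites$site_id[idx])
  }
  states <- data.table::rbindlist(pieces)
  states <- ct[states, on = "site_id"][, .(frag_id, chrom, pos, strand, context, p)]
  with_seed(seed, {
    states[, modified := stats::rbinom(.N, 1L, p) == 1L]
    states[, hydroxy := modified & stats::rbinom(.N, 1L, methylome$p_hydroxy) == 1L]
  })
  states[, p := NULL]
  data.table::setorderv(states, c("frag_id", "pos"))
  structure(list(fragments = fr, states = states, site_index = ct),
            class = "sim_molecules")
}

# Per-strand cytosine positions inside conversion-resistant motifs.
# Supports a small IUPAC subset in motifs (W, S, R, Y, N).
.motif_sites <- function(genome, motifs) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", S = "[CG]",
             R = "[AG]", Y = "[CT]", N = "[ACGT]")
  to_regex <- function(m) paste(iupac[strsplit(toupper(m), "")[[1]]], collapse = "")
  out <- list()
  for (k in seq_along(motifs)) {
    m <- names(motifs)[k]; mult <- motifs[[k]]
    for (nm in names(genome)) {
      s <- genome[[nm]]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") to_regex(m) else to_regex(revcomp(m))
        target <- if (strand == "+") "C" else "G"
        hits <- gregexpr(sprintf("(?=(%s))", pat), s, perl = TRUE)[[1]]
        if (hits[1] == -1L) next
        w <- nchar(m)
        offs <- unlist(lapply(as.integer(hits), function(h) {
          sub <- substring(s, h, h + w - 1L)
          h - 1L + which(strsplit(sub, "")[[1]] == target) - 1L
        }))
        if (length(offs))
          out[[length(out) + 1L]] <- data.table::data.table(
            chrom = nm, pos = as.integer(offs), strand = strand, mult = mult)
      }
    }
  }
  if (length(out) == 0) return(NULL)
  unique(data.table::rbindlist(out), by = c("chrom", "pos", "strand"))
}

#' Bisulfite-convert molecules with degradation
#'
#' Each molecule survives with probability
#' `(1 - beta_unmod)^k_u * (1 - beta_mod)^k_m`, where `k_u`/`k_m` count its
#' unmodified/modified cytosines (whole-molecule loss: a single break
#' anywhere removes the molecule from the sequencable pool). On surviving
#' molecules, each unmodified cytosine escapes conversion with the
#' effective context/motif/molecule-dependent failure probability and each
#' modified cytosine is over-converted with probability `gamma`. Every
#' stochastic outcome is recorded.
#'
#' @param molecules a [apply_methylome()] result.
#' @param protocol a [protocol_model()].
#' @param genome the [ref_genome()] (needed for resistant-motif matching).
#' @param seed RNG seed.
#' @return object of class `sim_conversion`: `fragments` gain `survived`
#'   and `poor` flags and a `copies` column (1 for survivors, 0 otherwise);
#'   `states` gain `meth_call` (NA for molecules that did not survive).
#' @export
bisulfite_convert <- function(molecules, protocol, genome, seed = NULL) {
  fr <- data.table::copy(molecules$fragments)
  st <- data.table::copy(molecules$states)
  kc <- st[, .(k_u = sum(!modified), k_m = sum(modified)), by = frag_id]
  fr[, `:=`(k_u = 0L, k_m = 0L)]
  fr[kc, `:=`(k_u = i.k_u, k_m = i.k_m), on = "frag_id"]
  with_seed(seed, {
    p_surv <- (1 - protocol$beta_unmod)^fr$k_u * (1 - protocol$beta_mod)^fr$k_m
    fr[, survived := stats::rbinom(.N, 1L, p_surv) == 1L]
    fr[, poor := stats::rbinom(.N, 1L, protocol$poor_fraction) == 1L]
    fr[, copies := as.integer(survived)]
    st[fr, `:=`(survived = i.survived, poor = i.poor), on = "frag_id"]
    st[, eps := ifelse(context == "CG", protocol$base_epsilon_CG,
                       protocol$base_epsilon_CH)]
    st[poor == TRUE, eps := protocol$poor_epsilon]
    if (!is.null(protocol$resistant_motifs)) {
      ms <- .motif_sites(genome, protocol$resistant_motifs)
      if (!is.null(ms)) {
        st[ms, eps := pmin(1, eps * i.mult), on = c("chrom", "pos", "strand")]
      }
    }
    st[, meth_call := NA]
    sel <- st$survived
    st$meth_call[sel & !st$modified] <-
      stats::rbinom(sum(sel & !st$modified), 1L, st$eps[sel & !st$modified]) == 1L
    st$meth_call[sel & st$modified] <-
      stats::rbinom(sum(sel & st$modified), 1L, 1 - protocol$gamma) == 1L
  })
  st[, c("eps", "survived", "poor") := NULL]
  structure(list(fragments = fr, states = st, site_index = molecules$site_index,
                 protocol = protocol),
            class = "sim_conversion")
}

#' PCR-amplify converted molecules
#'
#' Per cycle, each surviving molecule is copied with an efficiency that
#' depends on its *post-conversion* G+C fraction: the genomic Gs of the
#' molecule strand plus the cytosines it retained (methylated or
#' unconverted ones -- converted cytosines read as T and no longer
#' contribute). This is what couples amplification to methylation and to
#' conversion failure: methylated and poorly converted molecules keep more
#' cytosines, template a more GC-rich duplex, and are preferentially
#' amplified under a positive `efficiency_slope`. `cycles = 0` is the
#' identity.
#'
#' @param conversion a [bisulfite_convert()] result.
#' @param pcr a [pcr_model()].
#' @param genome the [ref_genome()].
#' @param seed RNG seed.
#' @return the conversion object with updated `copies` and a recorded
#'   `g_frac` (post-conversion G+C fraction) per fragment.
#' @export
pcr_amplify <- function(conversion, pcr, genome, seed = NULL) {
  fr <- data.table::copy(conversion$fragments)
  sub <- substring(unclass(genome)[fr$chrom], fr$start + 1L, fr$end)
  base <- ifelse(fr$strand == "+", "G", "C")
  gcnt <- nchar(sub) - nchar(
    mapply(function(s, b) gsub(b, "", s, fixed = TRUE), sub, base,
           USE.NAMES = FALSE))
  retained <- conversion$states[, .(n_ret = sum(meth_call %in% TRUE)), by = frag_id]
  fr[, n_retained := 0L]
  fr[retained, n_retained := i.n_ret, on = "frag_id"]
  fr[, g_frac := (gcnt + n_retained) / (end - start)]
  if (pcr$cycles > 0) {
    eff <- clamp(pcr$efficiency_base +
                   pcr$efficiency_slope * (fr$g_frac - pcr$g_ref), 0, 1)
    with_seed(seed, {
      ncop <- fr$copies
      for (cyc in seq_len(pcr$cycles)) {
        ncop <- if (pcr$stochastic)
          ncop + stats::rbinom(length(ncop), ncop, eff)
        else round(ncop * (1 + eff))
      }
      data.table::set(fr, j = "copies", value = as.numeric(ncop))
    })
  }
  conversion$fragments <- fr
  conversion$pcr <- pcr
  conversion
}

.CALL_CHARS <- matrix(c("z", "Z", "x", "X", "h", "H", "u", "U"), nrow = 2,
                      dimnames = list(NULL, c("CG", "CHG", "CHH", "U")))

#' Emit sequencing reads from converted molecules
#'
#' One read per molecule copy, taken from the molecule's 5' end (the left
#' edge of top-strand molecules, the right edge of bottom-strand ones);
#' molecules shorter than the read length are emitted whole. Call strings
#' are computed from the recorded per-cytosine truth; raw read sequences
#' carry the conversions in read orientation.
#'
#' When `n_reads` is given, that many molecules are drawn from the
#' amplified copy pool with probability proportional to copy number
#' (emulating the sequencer sampling a fixed yield from the library; the
#' same molecule can be drawn repeatedly, which is exactly what a PCR
#' duplicate is). Without it every copy is emitted, which is only sensible
#' for amplification-free runs.
#'
#' @param conversion a [bisulfite_convert()] (optionally
#'   [pcr_amplify()]-ed) result.
#' @param genome the [ref_genome()].
#' @param read_length read length in bases (default 100).
#' @param n_reads optional number of reads to sample from the copy pool.
#' @param seed RNG seed (used only when `n_reads` is given).
#' @return object of class `sim_reads`: list with `alignments`
#'   ([bs_alignments()]), `raw_reads` (named character), and `truth` (see
#'   [sim_truth()]).
#' @export
emit_reads <- function(conversion, genome, read_length = 100L,
                       n_reads = NULL, seed = NULL) {
  fr <- conversion$fragments[copies > 0L]
  st <- conversion$states
  if (nrow(fr) == 0) stop("no surviving molecules to sequence")
  if (!is.null(n_reads)) {
    with_seed(seed, {
      fr[, copies := as.integer(stats::rmultinom(1, n_reads, prob = copies))]
    })
    fr <- fr[copies > 0L]
  }
  top <- fr$strand == "+"
  rs <- ifelse(top, fr$start, pmax(fr$end - read_length, fr$start))
  re <- ifelse(top, pmin(fr$start + read_length, fr$end), fr$end)
  fr[, `:=`(rs = as.integer(rs), re = as.integer(re))]
  wid <- fr$re - fr$rs
  off <- c(0L, cumsum(wid))
  big <- rep(".", sum(wid))
  stf <- st[fr[, .(frag_id, rs, re, row = .I)], on = "frag_id", nomatch = NULL]
  stf <- stf[pos >= rs & pos < re]
  gi <- off[stf$row] + (stf$pos - stf$rs) + 1L
  big[gi] <- .CALL_CHARS[cbind(stf$meth_call + 1L, match(stf$context, colnames(.CALL_CHARS)))]
  bigs <- paste(big, collapse = "")
  call_strings <- substring(bigs, off[-length(off)] + 1L, off[-1])
  aln1 <- bs_alignments(data.frame(
    read_id = paste0("frag", fr$frag_id),
    chrom = fr$chrom, start = fr$rs, end = fr$re,
    bs_strand = ifelse(top, "OT", "OB"),
    call_string = call_strings,
    is_reverse = !top, is_duplicate = FALSE,
    stringsAsFactors = FALSE))
  # replicate one row per molecule copy
  rep_idx <- rep(seq_len(nrow(aln1)), fr$copies)
  copy_no <- sequence(fr$copies)
  aln <- aln1[rep_idx, , drop = FALSE]
  aln$read_id <- paste0(aln$read_id, "_c", copy_no)
  rownames(aln) <- NULL
  aln <- bs_alignments(aln)
  seqs <- .converted_seq(aln1, genome)
  seqs[!top] <- revcomp(seqs[!top])  # raw reads are in read orientation
  raw <- seqs[rep_idx]
  names(raw) <- aln$read_id
  structure(list(alignments = aln, raw_reads = raw,
                 truth = sim_truth(conversion)),
            class = "sim_reads")
}

#' Ground truth of a simulation
#'
#' Collects the per-fragment fate record and per-position truth:
#' `positions` aggregates molecule states *before* degradation (the
#' unbiased target a perfect measurement would recover), `global` holds
#' the realized pre-degradation global methylation by context.
#'
#' @param conversion a [bisulfite_convert()] result.
#' @return list with `fragments`, `positions`, `global`.
#' @export
sim_truth <- function(conversion) {
  st <- conversion$states
  pos <- st[, .(n_molecules = .N, n_modified = sum(modified)),
            by = .(chrom, pos, strand, context)]
  pos[, true_percent := 100 * n_modified / n_molecules]
  glob <- st[, .(true_percent = 100 * sum(modified) / .N), by = context]
  list(fragments = conversion$fragments, positions = pos[], global = glob[])
}

#' Run a full WGBS simulation
#'
#' Orchestrates fragmentation, methylome assignment, bisulfite conversion,
#' PCR and read emission under one root seed with named independent
#' substreams per stage (so changing, say, the PCR settings does not
#' perturb the fragmentation draws). An optional unmethylated spike-in
#' genome is fragmented and converted alongside the sample.
#'
#' @param genome a [ref_genome()].
#' @param methylome a [methylome_model()].
#' @param protocol a [protocol_model()].
#' @param pcr a [pcr_model()].
#' @param depth target fragment depth.
#' @param mean_length,length_sd fragment length distribution.
#' @param read_length read length.
#' @param seed root RNG seed (required for reproducibility).
#' @param spike_genome optional [ref_genome()] of unmethylated spike-in
#'   sequences (lambda/M13-like), simulated at `spike_depth`.
#' @param spike_depth depth for the spike (default `depth`).
#' @param n_reads optional sequencing yield; defaults to the number of
#'   surviving molecules whenever PCR cycles were run, so amplification
#'   biases representation rather than inflating depth without bound.
#' @return a `sim_reads` object whose alignments may span sample and spike
#'   references; element `genome` holds the combined reference.
#' @export
simulate_wgbs <- function(genome, methylome = methylome_model(),
                          protocol = protocol_model(), pcr = pcr_model(),
                          depth = 10, mean_length = 150L, length_sd = 20L,
                          read_length = 100L, seed = 1L,
                          spike_genome = NULL, spike_depth = NULL,
                          n_reads = NULL) {
  run_one <- function(g, meth, sd_off) {
    frags <- fragment_genome(g, mean_length, length_sd, depth = if (sd_off == 0) depth
                             else (spike_depth %||% depth),
                             seed = stage_seed(seed, "fragment") + sd_off)
    mol <- apply_methylome(frags, g, meth, seed = stage_seed(seed, "methylome") + sd_off)
    conv <- bisulfite_convert(mol, protocol, g,
                              seed = stage_seed(seed, "conversion") + sd_off)
    conv <- pcr_amplify(conv, pcr, g, seed = stage_seed(seed, "pcr") + sd_off)
    nr <- n_reads
    if (is.null(nr) && pcr$cycles > 0) nr <- sum(conv$fragments$survived)
    emit_reads(conv, g, read_length, n_reads = nr,
               seed = stage_seed(seed, "reads") + sd_off)
  }
  main <- run_one(genome, methylome, 0L)
  if (!is.null(spike_genome)) {
    spk <- run_one(spike_genome, methylome_model(p_mCG = 0, p_mCH = 0), 1L)
    spk$alignments$read_id <- paste0("spike_", spk$alignments$read_id)
    names(spk$raw_reads) <- paste0("spike_", names(spk$raw_reads))
    comb <- bs_alignments(rbind(main$alignments, spk$alignments))
    main <- structure(list(alignments = comb,
                           raw_reads = c(main$raw_reads, spk$raw_reads),
                           truth = main$truth, spike_truth = spk$truth),
                      class = "sim_reads")
    genome <- ref_genome(c(unclass(genome), unclass(spike_genome)))
  }
  main$genome <- genome
  main
}

#' Write a simulation bundle to disk
#'
#' FASTA reference, SAM alignments, FASTQ raw reads and tab-separated truth
#' tables, all plain text and byte-reproducible for a fixed seed.
#'
#' @param sim a [simulate_wgbs()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "reference.fa"))
  write_alignments(sim$alignments, file.path(dir, "reads.sam"), genome = sim$genome)
  write_raw_reads(sim$raw_reads, file.path(dir, "reads.fastq"))
  utils::write.table(sim$truth$positions, file.path(dir, "truth_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$fragments, file.path(dir, "truth_fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$global, file.path(dir, "truth_global.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
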