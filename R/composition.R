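.DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))

#' Mono- and dinucleotide composition table
#'
#' @param mono named counts for A, C, G, T.
#' @param di named counts for the 16 dinucleotides.
#' @return object of class `composition_table` with elements `mono`, `di`,
#'   `total_mono`, `total_di`, and fraction accessors via [composition_fractions()].
#' @export
composition_table <- function(mono, di) {
  m <- setNames(rep(0, 4), c("A", "C", "G", "T"))
  m[names(mono)] <- as.numeric(mono)
  d <- setNames(rep(0, 16), .DINUCS)
  d[names(di)] <- as.numeric(di)
  if (any(m < 0) || any(d < 0)) stop("negative composition count")
  structure(list(mono = m, di = d, total_mono = sum(m), total_di = sum(d)),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition_table:", format(x$total_mono, big.mark = ","), "bases,",
      format(x$total_di, big.mark = ","), "dinucleotides\n")
  pct <- round(100 * x$mono / x$total_mono, 2)
  cat(paste(sprintf("%s %.2f%%", names(pct), pct), collapse = "  "), "\n")
  invisible(x)
}

#' Fractions of a composition table
#'
#' @param x a [composition_table()].
#' @return list with `mono` and `di` fractions (counts over their totals).
#' @export
composition_fractions <- function(x) {
  list(mono = if (x$total_mono > 0) x$mono / x$total_mono else x$mono * NA,
       di = if (x$total_di > 0) x$di / x$total_di else x$di * NA)
}

.count_seqs <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  mono <- colSums(Biostrings::oligonucleotideFrequency(dss, 1L))
  di <- colSums(Biostrings::oligonucleotideFrequency(dss, 2L, step = 1L))
  composition_table(mono, di)
}

#' Genomic (expected) composition
#'
#' Tallies every base and every overlapping adjacent base pair within each
#' sequence record; no pairs are formed across record boundaries. Windows
#' containing N never contribute to the A/C/G/T tallies, so N handling is
#' symmetric between the genomic expectation and any observed table.
#'
#' @param genome a [ref_genome()].
#' @param exclude_n retained for interface clarity; N-containing windows are
#'   never attributable to an A/C/G/T k-mer, so the tallies are identical
#'   either way.
#' @return a [composition_table()].
#' @export
genome_composition <- function(genome, exclude_n = TRUE) {
  if (length(genome) == 0 || sum(nchar(genome)) == 0) stop("empty genome")
  .count_seqs(unclass(genome))
}

#' Composition observed under aligned-read footprints
#'
#' For each retained alignment, counts the mono- and overlapping
#' dinucleotides of the *genomic* sequence under the read footprint (not
#' the read sequence itself, where converted cytosines appear as thymines)
#' and aggregates across reads. A footprint of length L contributes L-1
#' pairs; a genomic position covered by k reads is counted k times, so the
#' table reflects coverage-weighted instances within the mapped data.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param genome a [ref_genome()].
#' @param include_duplicates count duplicate-flagged reads (default FALSE).
#' @param orientation `"reference"` (default) tallies every footprint in
#'   top-strand coordinates, the bam2nuc convention; `"parent"` tallies
#'   each footprint on the read's parent strand (reverse complement for
#'   OB/CTOB reads). Parent orientation is the sharper degradation
#'   diagnostic: bisulfite breakage tracks the cytosine content of the
#'   single-stranded molecule itself, and in reference coordinates the
#'   C-depletion of top-strand molecules partially cancels against the
#'   G-depletion of bottom-strand ones.
#' @return a [composition_table()].
#' @export
observed_composition <- function(aln, genome, include_duplicates = FALSE,
                                 orientation = c("reference", "parent")) {
  orientation <- match.arg(orientation)
  aln <- drop_duplicates(aln, include_duplicates)
  if (nrow(aln) == 0) stop("no alignments to tally")
  len <- nchar(unclass(genome))[aln$chrom]
  if (anyNA(len)) stop("alignment on unknown sequence: ", aln$chrom[is.na(len)][1])
  if (any(aln$start < 0 | aln$end > len)) stop("alignment beyond sequence bounds")
  seqs <- substring(unclass(genome)[aln$chrom], aln$start + 1L, aln$end)
  if (orientation == "parent") {
    bot <- parent_strand(aln) == "-"
    if (any(bot)) seqs[bot] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[bot])))
  }
  .count_seqs(seqs)
}

#' Observed-versus-expected composition bias report
#'
#' The bam2nuc-style diagnostic: for each of the 4 bases and 16
#' dinucleotides, the observed fraction in the mapped data, the genomic
#' expected fraction, and their log2 ratio. A depleted C row signals
#' bisulfite-induced degradation of C-rich fragments; C enrichment signals
#' poor conversion; G or A/T skews signal amplification and polymerase
#' bias. Ratios are only defined when both fractions are positive;
#' undefined entries are flagged, never fabricated.
#'
#' @param observed [composition_table()] from [observed_composition()].
#' @param expected [composition_table()] from [genome_composition()].
#' @return data.frame of class `composition_bias_report` with columns
#'   `kmer`, `k`, `genome_count`, `genome_pct`, `sample_count`,
#'   `sample_pct`, `log2_ratio`, `defined`.
#' @export
bias_report <- function(observed, expected) {
  if (observed$total_mono == 0 || expected$total_mono == 0)
    stop("degenerate composition table")
  of <- composition_fractions(observed); ef <- composition_fractions(expected)
  kmer <- c(names(ef$mono), names(ef$di))
  obs_c <- c(observed$mono, observed$di); exp_c <- c(expected$mono, expected$di)
  obs_f <- c(of$mono, of$di); exp_f <- c(ef$mono, ef$di)
  defined <- obs_f > 0 & exp_f > 0
  lr <- ifelse(defined, log2(obs_f / exp_f), NA_real_)
  out <- data.frame(
    kmer = kmer, k = nchar(kmer),
    genome_count = unname(exp_c), genome_pct = unname(100 * exp_f),
    sample_count = unname(obs_c), sample_pct = unname(100 * obs_f),
    log2_ratio = unname(lr), defined = unname(defined),
    stringsAsFactors = FALSE)
  class(out) <- c("composition_bias_report", "data.frame")
  out
}

#' Write a bias report as a tab-separated table
#'
#' Columns: (di)nucleotide, genome count, genome %, sample count, sample %,
#' log2 observed/expected ratio.
#'
#' @param report a [bias_report()] result.
#' @param path output path.
#' @export
write_bias_report <- function(report, path) {
  out <- data.frame(
    `(di)nucleotide` = report$kmer,
    genome_count = report$genome_count,
    genome_percent = sprintf("%.3f", report$genome_pct),
    sample_count = report$sample_count,
    sample_percent = sprintf("%.3f", report$sample_pct),
    log2_ratio = ifelse(report$defined, sprintf("%.4f", report$log2_ratio), "NA"),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-specific base-content wiggle track
#'
#' Emits a fixedStep wiggle track of the fraction of a chosen base on the
#' top strand per window. Bottom-strand G content equals top-strand C
#' content, so the two top-strand tracks suffice to describe both strands.
#' The final partial window is emitted with its own length as denominator
#' (as a separate fixedStep block, since its span differs).
#'
#' @param genome a [ref_genome()].
#' @param window window size in bases (>= 1).
#' @param base `"G"` or `"C"`.
#' @param path optional output path; when NULL the lines are returned only.
#' @return character vector of wiggle lines, invisibly when written.
#' @export
write_strand_content_wig <- function(genome, window, base = c("C", "G"),
                                     path = NULL) {
  base <- match.arg(base)
  if (window < 1) stop("window must be >= 1")
  lines <- character(0)
  for (nm in names(genome)) {
    s <- genome[[nm]]
    L <- nchar(s)
    w <- min(window, L)  # window longer than the sequence: one whole window
    nfull <- L %/% w
    rem <- L - nfull * w
    idx <- which(strsplit(s, "", fixed = TRUE)[[1]] == base)
    win_of <- ((idx - 1L) %/% w) + 1L
    cnt <- tabulate(win_of, nbins = nfull + (rem > 0))
    if (nfull > 0) {
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=1 step=%d span=%d", nm, w, w),
                 sprintf("%.6f", cnt[seq_len(nfull)] / w))
    }
    if (rem > 0) {
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         nm, nfull * w + 1L, rem, rem),
                 sprintf("%.6f", cnt[nfull + 1L] / rem))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
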