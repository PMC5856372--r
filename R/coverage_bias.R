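#' Strand-resolved read counts on a reference
#'
#' On references whose two strands differ strongly in cytosine content
#' (telomere, major satellite, mitochondrial DNA), bisulfite-induced
#' degradation of the C-rich strand shows up as an asymmetric read count
#' between original-top and original-bottom strands. Reads are assigned via
#' their bisulfite-strand provenance: OT and CTOT to the top strand, OB and
#' CTOB to the bottom.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param reference_name sequence to restrict to (NULL: all).
#' @param include_duplicates default TRUE: repeat references are analysed
#'   on raw, un-deduplicated data because their reads are not uniquely
#'   mappable.
#' @return list of class `strand_coverage`: `reference`, `top_count`,
#'   `bottom_count`, `top_proportion` (NA-flagged when no reads).
#' @export
strand_read_counts <- function(aln, reference_name = NULL,
                               include_duplicates = TRUE) {
  aln <- drop_duplicates(aln, include_duplicates)
  if (!is.null(reference_name)) aln <- aln[aln$chrom %in% reference_name, , drop = FALSE]
  top <- sum(aln$bs_strand %in% c("OT", "CTOT"))
  bottom <- sum(aln$bs_strand %in% c("OB", "CTOB"))
  structure(list(reference = reference_name %||% "all",
                 top_count = top, bottom_count = bottom,
                 top_proportion = if (top + bottom > 0) top / (top + bottom) else NA_real_),
            class = "strand_coverage")
}

#' @export
print.strand_coverage <- function(x, ...) {
  cat(sprintf("strand_coverage [%s]: top %d, bottom %d (top %.1f%%)\n",
              x$reference, x$top_count, x$bottom_count,
              100 * x$top_proportion))
  invisible(x)
}

#' Tandem-repeat unit histogram over raw reads
#'
#' Counts, per raw read, the non-overlapping occurrences of a repeat unit
#' (e.g. the telomeric hexamer TTAGGG, or TTTTAA for its bisulfite-converted
#' C-strand counterpart) scanning left to right, and histograms reads by
#' unit count. Runs on unmapped raw reads because high-copy tandem units do
#' not map. `orientation = "reversed"` uses the reverse complement of the
#' motif, the orientation seen by post-bisulfite (PBAT-type) libraries.
#'
#' @param reads named character vector of read sequences
#'   (see [read_raw_reads()]).
#' @param motif repeat unit (length >= 1).
#' @param orientation `"as_given"` or `"reversed"` (reverse complement).
#' @return object of class `tandem_histogram`: list with `motif` (as
#'   scanned), `orientation`, `counts` (named vector units-per-read ->
#'   number of reads, including the 0 bin), `min_units_applied`.
#' @export
tandem_unit_histogram <- function(reads, motif, orientation = c("as_given", "reversed")) {
  orientation <- match.arg(orientation)
  if (nchar(motif) < 1) stop("motif must have length >= 1")
  scan_motif <- if (orientation == "reversed") revcomp(motif) else motif
  hits <- gregexpr(scan_motif, reads, fixed = TRUE)
  n <- vapply(hits, function(m) if (m[1] == -1L) 0L else length(m), 0L)
  tab <- table(factor(n, levels = 0:max(n, 0)))
  counts <- setNames(as.integer(tab), names(tab))
  structure(list(motif = scan_motif, orientation = orientation,
                 counts = counts, min_units_applied = 0L),
            class = "tandem_histogram")
}

#' Drop low-unit-count reads from a tandem histogram
#'
#' Reads with only a few motif units are dominated by sequences of
#' non-telomeric origin (genomic TTTTAA runs are indistinguishable from
#' converted CCCTAA at low copy number), so bins below `min_units` are
#' removed. Idempotent.
#'
#' @param hist a [tandem_unit_histogram()].
#' @param min_units smallest unit count retained (default 5).
#' @return filtered `tandem_histogram` with `min_units_applied` recorded.
#' @export
filter_min_units <- function(hist, min_units = 5L) {
  if (min_units < 0) stop("min_units must be >= 0")
  units <- as.integer(names(hist$counts))
  hist$counts <- hist$counts[units >= min_units]
  hist$min_units_applied <- max(hist$min_units_applied, as.integer(min_units))
  hist
}

#' Windows of artefactually high coverage
#'
#' Non-overlapping genomic windows attracting an implausible number of
#' reads are likely alignment artefacts (collapsed repeats) and are
#' excluded from coverage analyses. A window is masked when *strictly more*
#' than `max_reads` reads start in it.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param genome a [ref_genome()].
#' @param window window size in bases (default 1000).
#' @param max_reads threshold; windows with count > max_reads are masked
#'   (default 1000).
#' @param include_duplicates default FALSE (genome-wide analyses run on
#'   deduplicated data).
#' @return intervals data.frame of masked windows (possibly empty).
#' @export
high_coverage_mask <- function(aln, genome, window = 1000L, max_reads = 1000L,
                               include_duplicates = FALSE) {
  if (window < 1) stop("window must be >= 1")
  aln <- drop_duplicates(aln, include_duplicates)
  out <- lapply(names(genome), function(nm) {
    L <- nchar(genome[[nm]])
    nwin <- ceiling(L / window)
    starts <- aln$start[aln$chrom == nm]
    if (length(starts) == 0) return(NULL)
    cnt <- tabulate(starts %/% window + 1L, nbins = nwin)
    hot <- which(cnt > max_reads)
    if (length(hot) == 0) return(NULL)
    genomic_intervals(nm, (hot - 1L) * window, pmin(hot * window, L))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(genomic_intervals(character(), integer(), integer())[0, ])
  do.call(rbind, out)
}

#' Drop reads starting inside masked intervals
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param mask intervals data.frame (e.g. from [high_coverage_mask()]).
#' @return the unmasked alignments.
#' @export
apply_mask <- function(aln, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(aln)
  drop <- rep(FALSE, nrow(aln))
  for (i in seq_len(nrow(mask))) {
    drop <- drop | (aln$chrom == mask$chrom[i] &
                      aln$start >= mask$start[i] & aln$start < mask$end[i])
  }
  aln[!drop, , drop = FALSE]
}

.overlaps_mask <- function(chrom, start, end, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, length(start)))
  hit <- rep(FALSE, length(start))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (chrom == mask$chrom[i] & start < mask$end[i] & end > mask$start[i])
  }
  hit
}

#' Read coverage as a function of tile G/C content
#'
#' The genome is partitioned into non-overlapping tiles; each tile's G (or
#' C) percentage is taken from the genomic sequence (not the read sequence,
#' where converted cytosines appear as thymines), each read is assigned to
#' the tile containing its footprint midpoint, counts are normalised by the
#' dataset's total retained read count, and tiles are grouped into
#' equal-width percentage bins. Empty bins are reported as missing, not
#' zero. The per-tile table is returned alongside the binned profile.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param genome a [ref_genome()].
#' @param tile tile width in bases (default 100).
#' @param bins number of equal-width percentage bins (default 100).
#' @param axis `"C"` or `"G"`.
#' @param mask optional intervals of artefact windows: reads starting in a
#'   masked window are dropped and tiles overlapping one are excluded.
#' @param include_duplicates default FALSE.
#' @return object of class `gc_coverage_profile`: list with `profile`
#'   (bin_low, bin_high, mean_norm_count, tile_count), `tiles` (per-tile
#'   chrom, start, end, pct, read_count, norm_count), `axis`,
#'   `total_reads`.
#' @export
tile_gc_coverage <- function(aln, genome, tile = 100L, bins = 100L,
                             axis = c("C", "G"), mask = NULL,
                             include_duplicates = FALSE) {
  axis <- match.arg(axis)
  if (tile < 1) stop("tile must be >= 1")
  aln <- drop_duplicates(aln, include_duplicates)
  aln <- apply_mask(aln, mask)
  tiles <- lapply(names(genome), function(nm) {
    L <- nchar(genome[[nm]])
    w <- min(tile, L)  # genome shorter than one tile: single whole tile
    starts <- seq.int(0L, L - 1L, by = w)
    ends <- pmin(starts + w, L)
    chars <- strsplit(genome[[nm]], "", fixed = TRUE)[[1]]
    idx <- which(chars == axis)
    cnt <- tabulate((idx - 1L) %/% w + 1L, nbins = length(starts))
    mids <- aln$start[aln$chrom == nm] + (aln$end - aln$start)[aln$chrom == nm] %/% 2L
    rc <- tabulate(mids %/% w + 1L, nbins = length(starts))
    data.frame(chrom = nm, start = starts, end = ends,
               pct = 100 * cnt / (ends - starts), read_count = rc,
               stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, tiles)
  tiles <- tiles[!.overlaps_mask(tiles$chrom, tiles$start, tiles$end, mask), , drop = FALSE]
  total <- nrow(aln)
  tiles$norm_count <- if (total > 0) tiles$read_count / total else NA_real_
  bw <- 100 / bins
  bin <- pmin(floor(tiles$pct / bw), bins - 1L)
  prof <- data.frame(bin_low = (0:(bins - 1)) * bw, bin_high = (1:bins) * bw)
  prof$mean_norm_count <- vapply(0:(bins - 1), function(b) {
    v <- tiles$norm_count[bin == b]
    if (length(v) == 0) NA_real_ else mean(v)
  }, 0)
  prof$tile_count <- vapply(0:(bins - 1), function(b) sum(bin == b), 0L)
  structure(list(profile = prof, tiles = tiles, axis = axis, total_reads = total),
            class = "gc_coverage_profile")
}

#' Relative coverage trend over a feature set
#'
#' Scales each feature to a fixed number of body bins, adds fixed-width
#' flanking bins on both sides, averages per-base read coverage per bin
#' across features, and divides by the dataset's mean genome-wide per-base
#' coverage so that 1 means no bias. Minus-strand features are flipped.
#' Features shorter than `body_bins` bases are skipped with a count; flank
#' bins outside the sequence are treated as missing for that feature.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param features intervals data.frame.
#' @param genome a [ref_genome()].
#' @param flank flank width in bases on each side (default 1000).
#' @param body_bins number of scaled bins across the feature body.
#' @param flank_bins number of fixed-width bins per flank
#'   (default `max(1, body_bins %/% 2)`).
#' @param include_duplicates default FALSE.
#' @return object of class `relative_coverage_trend`: data.frame with
#'   `bin` (1..flank_bins+body_bins+flank_bins), `zone` (upstream / body /
#'   downstream), `rel_coverage`; attributes `n_features_used`,
#'   `n_features_skipped`, `mean_genome_coverage`.
#' @export
feature_relative_coverage <- function(aln, features, genome, flank = 1000L,
                                      body_bins = 20L, flank_bins = NULL,
                                      include_duplicates = FALSE) {
  if (nrow(features) == 0) stop("feature set is empty")
  flank_bins <- flank_bins %||% max(1L, body_bins %/% 2L)
  aln <- drop_duplicates(aln, include_duplicates)
  lens <- nchar(unclass(genome))
  cov <- lapply(names(genome), function(nm) {
    sel <- aln$chrom == nm
    IRanges::coverage(IRanges::IRanges(start = aln$start[sel] + 1L,
                                       end = aln$end[sel]),
                      width = lens[[nm]])
  })
  names(cov) <- names(genome)
  mean_cov <- sum(vapply(cov, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                                S4Vectors::runLength(x)), 0)) /
    sum(lens)
  if (mean_cov == 0) stop("dataset has zero coverage")
  nb <- flank_bins + body_bins + flank_bins
  acc <- matrix(0, nrow = 0, ncol = nb)
  skipped <- 0L
  fw <- flank / flank_bins
  rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]
    if (!ch %in% names(cov)) { skipped <- skipped + 1L; next }
    s <- features$start[i]; e <- features$end[i]
    if (e - s < body_bins) { skipped <- skipped + 1L; next }
    body_edges <- round(seq(s, e, length.out = body_bins + 1))
    up_edges <- s - fw * (flank_bins:0)
    dn_edges <- e + fw * (0:flank_bins)
    edges <- c(up_edges[-length(up_edges)], body_edges, dn_edges[-1])
    lo <- round(edges[-length(edges)]); hi <- round(edges[-1])
    L <- lens[[ch]]
    vals <- rep(NA_real_, nb)
    ok <- lo >= 0 & hi <= L & hi > lo
    if (any(ok)) {
      v <- IRanges::Views(cov[[ch]],
                          start = lo[ok] + 1L, end = hi[ok])
      vals[ok] <- IRanges::viewMeans(v)
    }
    if (identical(features$strand[i], "-")) vals <- rev(vals)
    rows[[i]] <- vals
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no usable features (all skipped)")
  m <- do.call(rbind, rows)
  rel <- colMeans(m, na.rm = TRUE) / mean_cov
  out <- data.frame(
    bin = seq_len(nb),
    zone = c(rep("upstream", flank_bins), rep("body", body_bins),
             rep("downstream", flank_bins)),
    rel_coverage = rel)
  class(out) <- c("relative_coverage_trend", "data.frame")
  attr(out, "n_features_used") <- length(rows)
  attr(out, "n_features_skipped") <- skipped
  attr(out, "mean_genome_coverage") <- mean_cov
  out
}
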