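#' Filter reads with runs of unconverted non-CpG calls
#'
#' A read whose molecule escaped bisulfite conversion carries many
#' unconverted cytosines; because the CH (CHG + CHH) context is largely
#' unmethylated, several unconverted CH calls on one read are diagnostic of
#' a poorly converted molecule rather than of real methylation. The default
#' removes every read with three or more *consecutive* unconverted CH calls
#' (the 3xC filter). "Consecutive" means successive CH cytosine positions
#' along the read: non-cytosine positions and CpG positions do not break a
#' run, a converted CH call does. CpG calls never trigger removal.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param min_run minimum run length (consecutive mode) or minimum total
#'   count (total mode) of unconverted CH calls for removal; >= 1.
#' @param mode `"consecutive"` (default) or `"total"`.
#' @param count_unknown treat unknown-context calls (u/U) as CH
#'   (default TRUE, the conservative reading).
#' @return object of class `filter_outcome`: list with `kept` and `removed`
#'   alignment subsets and a `counters` vector (seen, kept, removed).
#' @export
filter_nonconversion_reads <- function(aln, min_run = 3L,
                                       mode = c("consecutive", "total"),
                                       count_unknown = TRUE) {
  mode <- match.arg(mode)
  if (min_run < 1) stop("min_run must be >= 1")
  cls_keep <- if (count_unknown) "[^xXhHuU]" else "[^xXhH]"
  upper <- if (count_unknown) "XHU" else "XH"
  ch_only <- gsub(cls_keep, "", aln$call_string)
  removed <- if (mode == "consecutive") {
    grepl(sprintf("[%s]{%d,}", upper, min_run), ch_only)
  } else {
    nchar(gsub(sprintf("[^%s]", upper), "", ch_only)) >= min_run
  }
  out <- list(kept = aln[!removed, , drop = FALSE],
              removed = aln[removed, , drop = FALSE],
              counters = c(seen = nrow(aln), kept = sum(!removed),
                           removed = sum(removed)))
  class(out) <- "filter_outcome"
  out
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf("filter_outcome: %d seen, %d kept, %d removed (%.2f%%)\n",
              x$counters[["seen"]], x$counters[["kept"]], x$counters[["removed"]],
              if (x$counters[["seen"]] > 0)
                100 * x$counters[["removed"]] / x$counters[["seen"]] else 0))
  invisible(x)
}

#' Mask leading read positions
#'
#' Random-primed (post-bisulfite) libraries carry chimeric starts and
#' position-dependent methylation bias at the read 5' end; the standard
#' remedy is to exclude the first bases of each read from analysis. The
#' first `n_start` call-string positions *in read orientation* are replaced
#' by `.`; for reverse-mapped reads this is the right edge of the
#' reference-oriented call string. The footprint is unchanged.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param n_start number of leading read bases to mask (default 4).
#' @return the alignments with masked call strings; attribute
#'   `n_fully_masked` counts reads shorter than `n_start`.
#' @export
trim_call_string <- function(aln, n_start = 4L) {
  if (n_start < 0) stop("n_start must be >= 0")
  if (n_start == 0 || nrow(aln) == 0) {
    attr(aln, "n_fully_masked") <- 0L
    return(aln)
  }
  cs <- aln$call_string
  len <- nchar(cs)
  k <- pmin(n_start, len)
  full <- n_start >= len
  if (any(full)) warning(sum(full), " read(s) fully masked by trimming")
  fwd <- !aln$is_reverse
  cs[fwd] <- paste0(strrep(".", k[fwd]), substring(cs[fwd], k[fwd] + 1L))
  cs[!fwd] <- paste0(substring(cs[!fwd], 1L, len[!fwd] - k[!fwd]),
                     strrep(".", k[!fwd]))
  aln$call_string <- cs
  attr(aln, "n_fully_masked") <- sum(full)
  aln
}

#' Zero per-cytosine methylation below a threshold
#'
#' The most common (and least effective) conversion-artefact remedy:
#' positions with methylation below the cutoff have their methylated calls
#' zeroed; positions at or above the cutoff are untouched. Idempotent.
#'
#' @param per_cytosine a [extract_per_cytosine()] table.
#' @param cutoff_percent threshold in \[0, 100\].
#' @return the filtered table.
#' @export
threshold_filter <- function(per_cytosine, cutoff_percent) {
  if (cutoff_percent < 0 || cutoff_percent > 100)
    stop("cutoff_percent must be in [0, 100]")
  low <- !is.na(per_cytosine$percent) & per_cytosine$percent < cutoff_percent
  per_cytosine$meth_count[low] <- 0L
  per_cytosine$percent[low] <- 0
  per_cytosine
}

#' Subtract an unmethylated-control background
#'
#' Normalises each cytosine's methylation against a whole-genome
#' bisulfite run of an unmethylated control of the same genome: whatever
#' signal the control shows at a position is conversion error (including
#' sequence-specific, conversion-resistant motifs, which no read filter can
#' remove because the same motif fails in every sample). Per matching
#' position the corrected percent is sample minus control, clipped at zero
#' by default. Positions absent from the control pass through unchanged and
#' are counted in the `n_uncontrolled` attribute.
#'
#' @param sample,control [extract_per_cytosine()] tables on the same genome.
#' @param clip_at_zero clip negative corrected values to 0 (default TRUE).
#'   Note that clipping makes aggregate means of corrected values biased
#'   upward under pure noise; for genome-wide residual estimates subtract
#'   the two global levels instead (see [global_methylation()]).
#' @param min_control_cov require at least this control coverage for a
#'   position to be corrected (default 0, i.e. no floor).
#' @return the sample table with `percent` replaced by the corrected value.
#' @export
background_subtract <- function(sample, control, clip_at_zero = TRUE,
                                min_control_cov = 0L) {
  if (!any(unique(sample$chrom) %in% unique(control$chrom)))
    stop("sample and control share no sequence names: coordinate frames differ")
  key <- function(x) paste(x$chrom, x$pos, x$strand, sep = "\r")
  idx <- match(key(sample), key(control))
  ctrl_pct <- control$percent[idx]
  ctrl_cov <- control$total_count[idx]
  usable <- !is.na(idx) & !is.na(ctrl_pct) & ctrl_cov >= min_control_cov
  n_unc <- sum(!usable)
  if (n_unc > 0)
    warning(n_unc, " position(s) absent from (or under-covered in) the control pass through uncorrected")
  corrected <- sample$percent
  corrected[usable] <- sample$percent[usable] - ctrl_pct[usable]
  if (clip_at_zero) corrected <- pmax(corrected, 0)
  sample$percent <- corrected
  attr(sample, "n_uncontrolled") <- n_unc
  sample
}

#' Conversion efficiency from an unmethylated spike-in
#'
#' Exogenous unmethylated DNA (lambda or M13 phage) spiked into the library
#' carries no true methylation, so every unconverted call on reads mapped
#' to the spike reference is a conversion failure. Efficiency is computed
#' over all cytosine contexts with a per-context breakdown.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param spike_chrom name of the spike reference sequence; NULL uses all
#'   alignments (assumes the file is already restricted to the spike).
#' @param include_duplicates count duplicate-flagged reads (default TRUE;
#'   spike coverage is usually shallow and unamplified-copy filtering is
#'   done upstream where wanted).
#' @return object of class `conversion_estimate`: list with
#'   `converted_calls`, `unconverted_calls`, `efficiency` (fraction),
#'   `by_context` data.frame, `defined` flag.
#' @export
spike_in_conversion <- function(aln, spike_chrom = NULL, include_duplicates = TRUE) {
  aln <- drop_duplicates(aln, include_duplicates)
  if (!is.null(spike_chrom)) aln <- aln[aln$chrom %in% spike_chrom, , drop = FALSE]
  chars <- strsplit(paste(aln$call_string, collapse = ""), "", fixed = TRUE)[[1]]
  cnt <- function(ch) sum(chars == ch)
  ctx <- data.frame(
    context = c("CG", "CHG", "CHH", "unknown"),
    converted = c(cnt("z"), cnt("x"), cnt("h"), cnt("u")),
    unconverted = c(cnt("Z"), cnt("X"), cnt("H"), cnt("U")))
  ctx$efficiency <- with(ctx, ifelse(converted + unconverted > 0,
                                     converted / (converted + unconverted), NA_real_))
  conv <- sum(ctx$converted); unconv <- sum(ctx$unconverted)
  out <- list(converted_calls = conv, unconverted_calls = unconv,
              efficiency = if (conv + unconv > 0) conv / (conv + unconv) else NA_real_,
              by_context = ctx, defined = conv + unconv > 0)
  class(out) <- "conversion_estimate"
  out
}

#' @export
print.conversion_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("conversion_estimate: no cytosine calls, efficiency undefined\n")
  } else {
    cat(sprintf("conversion_estimate: %.3f%% (%d converted / %d unconverted)\n",
                100 * x$efficiency, x$converted_calls, x$unconverted_calls))
    print(x$by_context, row.names = FALSE)
  }
  invisible(x)
}
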