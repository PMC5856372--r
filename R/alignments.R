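#' Bisulfite alignments container
#'
#' An aligned bisulfite read is an ungapped reference footprint plus a
#' per-reference-position methylation call string in the usual bisulfite
#' aligner dialect: `z/Z` CpG, `x/X` CHG, `h/H` CHH, `u/U` unknown context,
#' `.` not a cytosine on the read's parent strand. Uppercase means
#' unconverted (read as methylated), lowercase converted. `bs_strand`
#' records the bisulfite-strand provenance: `OT`/`OB` original top/bottom
#' strand, `CTOT`/`CTOB` their complementary PCR products. The call string
#' is stored left-to-right in reference orientation; `is_reverse` marks
#' reads whose 5' end sits at the right edge of the footprint.
#'
#' @param df data.frame with columns `read_id`, `chrom`, `start` (0-based),
#'   `end`, `bs_strand`, `call_string`, `is_reverse`, `is_duplicate`.
#' @return validated `bs_alignments` data.frame.
#' @export
bs_alignments <- function(df) {
  need <- c("read_id", "chrom", "start", "end", "bs_strand", "call_string",
            "is_reverse", "is_duplicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing alignment columns: ", paste(miss, collapse = ", "))
  if (!all(df$bs_strand %in% c("OT", "OB", "CTOT", "CTOB")))
    stop("bs_strand must be OT, OB, CTOT or CTOB")
  if (any(nchar(df$call_string) != df$end - df$start))
    stop("call string length must equal footprint length")
  if (any(grepl("[^zZxXhHuU.]", df$call_string)))
    stop("call string contains characters outside the z/Z x/X h/H u/U '.' dialect")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("bs_alignments", "data.frame")
  df
}

#' Parent (original) strand of each alignment
#'
#' OT and CTOT reads observe cytosines of the top genomic strand, OB and
#' CTOB those of the bottom strand.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @return character vector of `+`/`-`.
#' @export
parent_strand <- function(aln) {
  ifelse(aln$bs_strand %in% c("OT", "CTOT"), "+", "-")
}

drop_duplicates <- function(aln, include_duplicates) {
  if (include_duplicates) aln else aln[!aln$is_duplicate, , drop = FALSE]
}

.bs_strand_from_tags <- function(xr, xg) {
  # genome conversion (XG) CT -> parent strand is top, GA -> bottom;
  # read conversion (XR) distinguishes the original strand from its
  # complementary PCR product.
  out <- rep(NA_character_, length(xr))
  out[xg == "CT" & xr == "CT"] <- "OT"
  out[xg == "CT" & xr == "GA"] <- "CTOT"
  out[xg == "GA" & xr == "CT"] <- "OB"
  out[xg == "GA" & xr == "GA"] <- "CTOB"
  out
}

#' Read bisulfite alignments from SAM/BAM
#'
#' Consumes SAM or BAM files carrying the XM (call string), XR (read
#' conversion) and XG (genome conversion) tags. Only ungapped alignments
#' (CIGAR a single match run) are accepted; gapped or clipped records are
#' skipped and counted in the `n_skipped_gapped` attribute rather than
#' silently mis-assigned. The duplicate flag (0x400) and the reverse flag
#' (0x10) are propagated.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return [bs_alignments()] with attribute `n_skipped_gapped`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("XM", "XR", "XG"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(res$pos)
  qname <- res$qname[mapped]; flag <- res$flag[mapped]
  rname <- as.character(res$rname)[mapped]; pos <- res$pos[mapped]
  cigar <- res$cigar[mapped]
  xm <- res$tag$XM[mapped]; xr <- res$tag$XR[mapped]; xg <- res$tag$XG[mapped]
  if (length(qname) == 0) {
    out <- bs_alignments(data.frame(
      read_id = character(), chrom = character(), start = integer(),
      end = integer(), bs_strand = character(), call_string = character(),
      is_reverse = logical(), is_duplicate = logical()))
    attr(out, "n_skipped_gapped") <- 0L
    return(out)
  }
  if (is.null(xm) || anyNA(xm))
    stop("record without XM call-string tag: ",
         qname[if (is.null(xm)) 1L else which(is.na(xm))[1]])
  if (is.null(xr) || is.null(xg) || anyNA(xr) || anyNA(xg))
    stop("record without XR/XG conversion tags")
  ungapped <- grepl("^[0-9]+M$", cigar)
  n_skip <- sum(!ungapped)
  if (n_skip > 0)
    warning(n_skip, " gapped/clipped alignment(s) skipped (v1 accepts ungapped only)")
  keep <- ungapped
  width <- as.integer(sub("M$", "", cigar[keep]))
  out <- bs_alignments(data.frame(
    read_id = qname[keep],
    chrom = rname[keep],
    start = pos[keep] - 1L,           # SAM is 1-based
    end = pos[keep] - 1L + width,
    bs_strand = .bs_strand_from_tags(xr[keep], xg[keep]),
    call_string = xm[keep],
    is_reverse = bitwAnd(flag[keep], 16L) > 0L,
    is_duplicate = bitwAnd(flag[keep], 1024L) > 0L,
    stringsAsFactors = FALSE))
  attr(out, "n_skipped_gapped") <- n_skip
  out
}

# Reference-oriented read sequence implied by a call string: lowercase calls
# are bisulfite-converted (C->T on the top parent strand, G->A on the
# bottom); uppercase calls retain the genomic base.
.converted_seq <- function(aln, genome) {
  vapply(seq_len(nrow(aln)), function(i) {
    s <- substring(genome[[aln$chrom[i]]], aln$start[i] + 1L, aln$end[i])
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    cc <- strsplit(aln$call_string[i], "", fixed = TRUE)[[1]]
    conv <- cc %in% c("z", "x", "h", "u")
    ch[conv] <- if (aln$bs_strand[i] %in% c("OT", "CTOT")) "T" else "A"
    paste(ch, collapse = "")
  }, character(1))
}

#' Write bisulfite alignments as SAM
#'
#' Emits a headered SAM file with XM/XR/XG tags. When `genome` is given the
#' SEQ field carries the bisulfite-converted read sequence implied by the
#' call string; otherwise SEQ is `*`.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param path output path (`.sam`).
#' @param genome optional [ref_genome()] used to reconstruct read sequences.
#' @export
write_alignments <- function(aln, path, genome = NULL) {
  chroms <- unique(aln$chrom)
  if (!is.null(genome)) chroms <- names(genome)
  lens <- if (!is.null(genome)) nchar(unclass(genome))[chroms]
          else vapply(chroms, function(cc) max(aln$end[aln$chrom == cc]), 0L)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(lens)))
  n <- nrow(aln)
  seqf <- if (is.null(genome)) rep("*", n) else .converted_seq(aln, genome)
  qual <- if (is.null(genome)) rep("*", n) else strrep("I", nchar(seqf))
  flag <- 16L * aln$is_reverse + 1024L * aln$is_duplicate
  xr <- ifelse(aln$bs_strand %in% c("OT", "OB"), "CT", "GA")
  xg <- ifelse(aln$bs_strand %in% c("OT", "CTOT"), "CT", "GA")
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tXM:Z:%s\tXR:Z:%s\tXG:Z:%s",
                 aln$read_id, flag, aln$chrom, aln$start + 1L,
                 aln$end - aln$start, seqf, qual, aln$call_string, xr, xg)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read raw reads (FASTQ or plain sequence list)
#'
#' Only the sequence field is used; this is the input to tandem-repeat
#' counting, which runs on unmapped reads because tandem hexamer units are
#' not mappable.
#'
#' @param path FASTQ file (`.fastq`/`.fq`) or plain text with one sequence
#'   per line.
#' @return named character vector of uppercase read sequences.
#' @export
read_raw_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fastq", "fq")) {
    dss <- Biostrings::readDNAStringSet(path, format = "fastq")
    out <- toupper(as.character(dss))
    names(out) <- sub("\\s.*$", "", names(dss))
  } else {
    lines <- readLines(path)
    out <- toupper(lines[nzchar(lines)])
    names(out) <- paste0("read_", seq_along(out))
  }
  if (any(grepl("[^ACGTN]", out))) stop("raw read with illegal character in ", path)
  out
}

#' Write raw reads as FASTQ
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @export
write_raw_reads <- function(reads, path) {
  ids <- names(reads) %||% paste0("read_", seq_along(reads))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+",
                             strrep("I", nchar(reads)))), path)
  invisible(path)
}
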