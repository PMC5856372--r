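#' Genomic intervals
#'
#' Plain data.frame of 0-based, half-open intervals. Strand is `+`, `-` or
#' `*` (unstranded). Used for features (CpG islands, DMRs), tiles, probes
#' and coverage masks.
#'
#' @param chrom,start,end,strand,name interval fields; `strand` and `name`
#'   are recycled.
#' @param genome optional [ref_genome()] to bound-check against.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NA_character_,
                              genome = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   name = rep_len(as.character(name), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!is.null(genome)) {
    len <- nchar(unclass(genome))[df$chrom]
    if (anyNA(len)) stop("interval on unknown sequence: ",
                         df$chrom[is.na(len)][1])
    if (any(df$end > len)) stop("interval end beyond sequence length")
  }
  df
}

#' Read intervals from a BED3+ file
#'
#' BED coordinates are already 0-based half-open and are kept as such.
#' The strand column (column 6) is honoured when present. A record with
#' `start >= end` is a format error reported with its line number.
#'
#' @param path path to a BED file.
#' @return data.frame as from [genomic_intervals()].
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED record with fewer than 3 fields at line ",
                        lineno[which(nf < 3)[1]])
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinate at line ", lineno[which(is.na(start) | is.na(end))[1]])
  bad <- start >= end
  if (any(bad)) stop("BED record with start >= end at line ", lineno[which(bad)[1]])
  strand <- get(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  genomic_intervals(get(1), start, end, strand = strand, name = get(4))
}

#' Write intervals as BED
#'
#' @param intervals data.frame from [genomic_intervals()].
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  name <- intervals$name %||% NA_character_
  name[is.na(name)] <- "."
  strand <- intervals$strand %||% "*"
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, 0L, ifelse(strand == "*", ".", strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
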