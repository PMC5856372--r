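#' Reference genome container
#'
#' A reference genome is stored as a named character vector of uppercase
#' nucleotide sequences over the alphabet A, C, G, T, N. It is the coordinate
#' frame for every other object in the package; all coordinates are 0-based
#' and half-open.
#'
#' @param records named character vector of sequences (lowercase accepted,
#'   upcased on construction).
#' @return an object of class `ref_genome`.
#' @export
ref_genome <- function(records) {
  if (length(records) == 0) stop("a reference genome needs at least one sequence")
  nm <- names(records)
  if (is.null(nm) || any(!nzchar(nm))) stop("sequence names must be non-empty")
  if (anyDuplicated(nm)) stop("duplicated sequence name: ", nm[duplicated(nm)][1])
  records <- toupper(records)
  bad <- grepl("[^ACGTN]", records)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(records[i], regexpr("[^ACGTN]", records[i]))
    stop("illegal character '", ch, "' in sequence '", nm[i], "'")
  }
  structure(records, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome with", length(x), "sequence(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  for (nm in utils::head(names(x), 10))
    cat(sprintf("  %s  %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Sequences are upcased and validated against the A/C/G/T/N alphabet; input
#' order is preserved. On an alphabet violation the error names the first
#' offending line of the file.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a [ref_genome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  recs <- toupper(as.character(dss))
  names(recs) <- sub("\\s.*$", "", names(dss))
  bad <- grepl("[^ACGTN]", recs)
  if (any(bad)) {
    lines <- readLines(path)
    off <- which(!startsWith(lines, ">") & grepl("[^ACGTNacgtn]", lines))
    stop("illegal character in FASTA '", path, "' at line ",
         if (length(off)) off[1] else NA_integer_)
  }
  ref_genome(recs)
}

#' Write a reference genome to FASTA
#'
#' @param genome a [ref_genome()].
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

.ctx_from_next <- function(n1, n2) {
  # cytosine context from the two downstream bases on the same strand
  ctx <- rep("U", length(n1))
  h1 <- n1 %in% c("A", "C", "T")
  ctx[n1 == "G"] <- "CG"
  ctx[h1 & n2 == "G"] <- "CHG"
  ctx[h1 & n2 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

#' Per-strand cytosine positions and contexts of a genome
#'
#' Lists every cytosine on both strands with its trinucleotide context
#' (CG, CHG, CHH, or U when the context runs off the sequence end or into
#' an N). Bottom-strand cytosines are genomic Gs; their context is read
#' leftwards on the complement.
#'
#' @param genome a [ref_genome()].
#' @return a `data.table` with columns `chrom`, `pos` (0-based), `strand`
#'   (`+`/`-`), `context`.
#' @export
cytosine_context_table <- function(genome) {
  out <- lapply(names(genome), function(nm) {
    b <- strsplit(genome[[nm]], "", fixed = TRUE)[[1]]
    L <- length(b)
    pad <- function(v) c(v, rep(NA_character_, 2L))
    bp <- pad(b)
    top <- which(b == "C")
    bot <- which(b == "G")
    dt_top <- if (length(top)) data.table::data.table(
      chrom = nm, pos = top - 1L, strand = "+",
      context = .ctx_from_next(bp[top + 1L], bp[top + 2L])
    )
    dt_bot <- if (length(bot)) {
      comp_or_na <- function(v) ifelse(is.na(v), NA_character_, unname(.complement[v]))
      n1 <- comp_or_na(c(NA_character_, NA_character_, b)[bot + 1L])  # base at bot-1
      n2 <- comp_or_na(c(NA_character_, NA_character_, b)[bot])      # base at bot-2
      data.table::data.table(
        chrom = nm, pos = bot - 1L, strand = "-",
        context = .ctx_from_next(n1, n2)
      )
    }
    data.table::rbindlist(list(dt_top, dt_bot))
  })
  dt <- data.table::rbindlist(out)
  data.table::setorderv(dt, c("chrom", "pos", "strand"))
  dt[]
}

#' Genomic cytosine-context abundance
#'
#' Counts cytosines by context (both strands) and reports the CH:CG
#' abundance ratio, the quantity that makes non-CG conversion artefacts so
#' visible: in CpG-depleted genomes the CH context outnumbers CG more than
#' twentyfold, so even a small per-cytosine conversion-failure rate yields
#' far more false-positive CH calls than CG calls.
#'
#' @param genome a [ref_genome()].
#' @return list with `counts` (named: CG, CHG, CHH, U) and `ch_cg_ratio`.
#' @export
context_composition <- function(genome) {
  ct <- cytosine_context_table(genome)
  counts <- c(CG = 0, CHG = 0, CHH = 0, U = 0)
  tab <- table(ct$context)
  counts[names(tab)] <- as.numeric(tab)
  ch <- counts[["CHG"]] + counts[["CHH"]]
  list(counts = counts,
       ch_cg_ratio = if (counts[["CG"]] > 0) ch / counts[["CG"]] else NA_real_)
}
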