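# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive scalar loops so they share no code path with the
# implementations they check.

make_aln <- function(call_string, start = 0L, chrom = "ref", bs_strand = "OT",
                     is_reverse = bs_strand %in% c("OB", "CTOB"),
                     is_duplicate = FALSE, read_id = NULL) {
  n <- if (length(call_string) == 0) 0L
       else max(length(call_string), length(start), length(chrom), length(bs_strand))
  call_string <- rep_len(call_string, n)
  bs_alignments(data.frame(
    read_id = rep_len(read_id %||% paste0("r", seq_len(n)), n),
    chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start, n) + nchar(call_string)),
    bs_strand = rep_len(bs_strand, n),
    call_string = call_string,
    is_reverse = rep_len(is_reverse, n),
    is_duplicate = rep_len(is_duplicate, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sliding-window k-mer tally, one window at a time, N windows skipped
oracle_count_kmers <- function(seqs, k) {
  out <- new.env()
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) < k) next
    for (i in 1:(length(ch) - k + 1)) {
      km <- paste(ch[i:(i + k - 1)], collapse = "")
      if (grepl("N", km, fixed = TRUE)) next
      out[[km]] <- (out[[km]] %||% 0) + 1
    }
  }
  unlist(as.list(out))
}

# scalar scan of a call string for the non-conversion filter
oracle_nonconv_removed <- function(call, min_run, mode = "consecutive",
                                   count_unknown = TRUE) {
  ch_lower <- if (count_unknown) c("x", "h", "u") else c("x", "h")
  ch_upper <- if (count_unknown) c("X", "H", "U") else c("X", "H")
  run <- 0L; best <- 0L; total <- 0L
  for (c0 in strsplit(call, "")[[1]]) {
    if (c0 %in% ch_upper) {
      run <- run + 1L; total <- total + 1L
      best <- max(best, run)
    } else if (c0 %in% ch_lower) {
      run <- 0L
    }
    # '.', z, Z and (when excluded) u/U neither extend nor break a run
  }
  if (mode == "consecutive") best >= min_run else total >= min_run
}

# left-to-right non-overlapping motif scan
oracle_tandem_count <- function(seq, motif) {
  n <- 0L; i <- 1L
  w <- nchar(motif)
  while (i + w - 1L <= nchar(seq)) {
    if (substring(seq, i, i + w - 1L) == motif) {
      n <- n + 1L; i <- i + w
    } else i <- i + 1L
  }
  n
}

# greedy partition of sorted positions into n-position windows
oracle_tile_bounds <- function(pos, n) {
  pos <- sort(pos)
  out <- NULL
  while (length(pos) >= n) {
    grp <- pos[1:n]
    out <- rbind(out, c(grp[1], grp[n] + 1L))
    pos <- pos[-(1:n)]
  }
  out
}

random_call_string <- function(len, p_upper = 0.3) {
  pool <- c(".", "z", "Z", "x", "X", "h", "H", "u", "U")
  prob <- c(0.5, rep(c((1 - p_upper) * 0.125, p_upper * 0.125), 4))
  paste(sample(pool, len, replace = TRUE, prob = prob), collapse = "")
}

random_seq <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
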