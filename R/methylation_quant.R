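#' Per-cytosine methylation from call strings
#'
#' Every non-`.` call increments the total at its reference position on the
#' read's parent strand; an uppercase call additionally increments the
#' methylated count. Context is taken from the call character class (z/Z
#' CpG, x/X CHG, h/H CHH, u/U unknown). If reads disagree on the context of
#' a position (possible near sequence variants), the majority context is
#' reported and the conflict counted.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param contexts contexts to retain (default CG, CHG, CHH; `"U"` adds
#'   unknown-context calls).
#' @param include_duplicates default FALSE.
#' @return data.frame of class `per_cytosine` with columns `chrom`, `pos`
#'   (0-based), `strand`, `context`, `meth_count`, `total_count`,
#'   `percent`; attribute `n_context_conflicts`.
#' @export
extract_per_cytosine <- function(aln, contexts = c("CG", "CHG", "CHH"),
                                 include_duplicates = FALSE) {
  aln <- drop_duplicates(aln, include_duplicates)
  empty <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      context = character(), meth_count = integer(),
                      total_count = integer(), percent = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("per_cytosine", "data.frame")
  attr(empty, "n_context_conflicts") <- 0L
  if (nrow(aln) == 0) return(empty)
  lens <- nchar(aln$call_string)
  ch <- unlist(strsplit(aln$call_string, "", fixed = TRUE), use.names = FALSE)
  keep <- ch != "."
  if (!any(keep)) return(empty)
  dt <- data.table::data.table(
    chrom = rep(aln$chrom, lens)[keep],
    pos = (unlist(lapply(lens, seq_len), use.names = FALSE) - 1L +
             rep(aln$start, lens))[keep],
    strand = rep(parent_strand(aln), lens)[keep],
    char = ch[keep])
  ctx_map <- c(z = "CG", Z = "CG", x = "CHG", X = "CHG",
               h = "CHH", H = "CHH", u = "U", U = "U")
  dt[, context := ctx_map[char]]
  dt[, meth := char %in% c("Z", "X", "H", "U")]
  by_ctx <- dt[, .(meth_count = sum(meth), n = .N),
               by = .(chrom, pos, strand, context)]
  data.table::setorderv(by_ctx, c("chrom", "pos", "strand", "n"),
                        order = c(1L, 1L, 1L, -1L))
  agg <- by_ctx[, .(context = context[1], n_ctx = .N,
                    meth_count = sum(meth_count), total_count = sum(n)),
                by = .(chrom, pos, strand)]
  n_conflict <- sum(agg$n_ctx > 1)
  if (n_conflict > 0)
    warning(n_conflict, " position(s) with conflicting context classes; majority reported")
  agg[, n_ctx := NULL]
  agg <- agg[context %in% contexts]
  agg[, percent := ifelse(total_count > 0, 100 * meth_count / total_count, NA_real_)]
  data.table::setorderv(agg, c("chrom", "pos", "strand"))
  out <- as.data.frame(agg)
  class(out) <- c("per_cytosine", "data.frame")
  attr(out, "n_context_conflicts") <- n_conflict
  out
}

#' Region methylation: pooled calls versus per-cytosine mean
#'
#' Two quantification strategies for a region of interest. `pooled` counts
#' all methylation calls in the region irrespective of position and depth
#' (100 * sum(meth) / sum(total)); `cytosine_mean` computes each cytosine's
#' percentage first and averages those. When read coverage is correlated
#' with methylation state -- as bisulfite-induced degradation of
#' unmethylated fragments makes it -- pooling weights highly covered
#' (highly methylated) cytosines more and inherits the coverage bias,
#' whereas the per-cytosine mean gives every covered cytosine equal weight.
#' A region is reported only when its total call count reaches
#' `min_region_obs`; `min_cytosine_cov` optionally drops shallow cytosines
#' first (a practice that *reinforces* the coverage bias).
#'
#' @param per_cytosine a [extract_per_cytosine()] table.
#' @param regions intervals data.frame.
#' @param strategy `"pooled"` or `"cytosine_mean"`.
#' @param min_region_obs minimum total calls per region (default 3).
#' @param min_cytosine_cov minimum per-cytosine coverage (default 0).
#' @param contexts contexts included (default CG).
#' @return data.frame of class `region_methylation`: region columns plus
#'   `strategy`, `value` (percent, NA when excluded), `n_cytosines_used`,
#'   `n_calls_used`, `included`.
#' @export
region_methylation <- function(per_cytosine, regions,
                               strategy = c("pooled", "cytosine_mean"),
                               min_region_obs = 3L, min_cytosine_cov = 0L,
                               contexts = "CG") {
  strategy <- match.arg(strategy)
  pc <- data.table::as.data.table(per_cytosine)
  pc <- pc[context %in% contexts & total_count >= max(1L, min_cytosine_cov)]
  reg <- data.table::as.data.table(regions)
  reg[, region_id := .I]
  pc[, `:=`(rstart = pos, rend = pos + 1L)]
  data.table::setkey(reg, chrom, start, end)
  ov <- data.table::foverlaps(pc, reg, by.x = c("chrom", "rstart", "rend"),
                              nomatch = NULL)
  stats <- ov[, .(
    pooled = 100 * sum(meth_count) / sum(total_count),
    cytosine_mean = mean(percent),
    n_cytosines_used = .N,
    n_calls_used = sum(total_count)
  ), by = region_id]
  out <- as.data.frame(regions)
  out$strategy <- strategy
  idx <- match(seq_len(nrow(out)), stats$region_id)
  out$value <- if (strategy == "pooled") stats$pooled[idx] else stats$cytosine_mean[idx]
  out$n_cytosines_used <- ifelse(is.na(idx), 0L, stats$n_cytosines_used[idx])
  out$n_calls_used <- ifelse(is.na(idx), 0L, stats$n_calls_used[idx])
  out$included <- out$n_calls_used >= min_region_obs
  out$value[!out$included] <- NA_real_
  class(out) <- c("region_methylation", "data.frame")
  out
}

#' Global methylation level
#'
#' 100 * sum(meth) / sum(total) over all positions in the chosen context
#' set, i.e. the coverage-weighted mean of per-cytosine percentages.
#'
#' @param per_cytosine a [extract_per_cytosine()] table.
#' @param contexts context set (default CG).
#' @return percent (NA with a warning when there are no calls).
#' @export
global_methylation <- function(per_cytosine, contexts = "CG") {
  sel <- per_cytosine$context %in% contexts
  tot <- sum(per_cytosine$total_count[sel])
  if (tot == 0) {
    warning("no calls in context(s) ", paste(contexts, collapse = ","),
            "; global level undefined")
    return(NA_real_)
  }
  100 * sum(per_cytosine$meth_count[sel]) / tot
}

#' Coverage-weighted mean of (possibly corrected) percentages
#'
#' For tables whose `percent` column no longer equals
#' `100 * meth_count / total_count` (e.g. after [background_subtract()]),
#' the global level is the coverage-weighted mean of the percentages.
#'
#' @param per_cytosine a [extract_per_cytosine()]-style table.
#' @param contexts context set.
#' @return percent.
#' @export
mean_percent <- function(per_cytosine, contexts = c("CHG", "CHH")) {
  sel <- per_cytosine$context %in% contexts & !is.na(per_cytosine$percent)
  if (!any(sel)) return(NA_real_)
  stats::weighted.mean(per_cytosine$percent[sel], per_cytosine$total_count[sel])
}

#' Non-overlapping tiles containing a fixed number of cytosines
#'
#' Fixed-cytosine-count measurement windows (e.g. 50- or 150-cytosine
#' tiles) adapt their genomic width to the local cytosine density, so every
#' probe rests on the same number of measurable positions. Per chromosome,
#' consecutive windows of exactly `n` context positions are formed; a
#' trailing remainder of fewer than `n` positions is discarded and counted.
#'
#' @param x a [ref_genome()] (positions from the sequence) or a
#'   [extract_per_cytosine()] table (positions observed in the data).
#' @param n cytosines per tile (>= 1).
#' @param context context of the positions (default CG).
#' @return intervals data.frame (window bounds run from the first to one
#'   past the last contained position); attribute `n_discarded_positions`.
#' @export
cytosine_tiles <- function(x, n, context = "CG") {
  if (n < 1) stop("n must be >= 1")
  pos_tab <- if (inherits(x, "ref_genome")) {
    ct <- as.data.frame(cytosine_context_table(x))
    ct[ct$context %in% context, c("chrom", "pos")]
  } else {
    x <- as.data.frame(x)
    unique(x[x$context %in% context, c("chrom", "pos")])
  }
  pos_tab <- pos_tab[order(pos_tab$chrom, pos_tab$pos), ]
  discarded <- 0L
  out <- lapply(split(pos_tab$pos, pos_tab$chrom), function(p) {
    ntile <- length(p) %/% n
    discarded <<- discarded + (length(p) - ntile * n)
    if (ntile == 0) return(NULL)
    grp <- rep(seq_len(ntile), each = n)
    p <- p[seq_len(ntile * n)]
    data.frame(start = tapply(p, grp, min), end = tapply(p, grp, max) + 1L)
  })
  chroms <- rep(names(out), vapply(out, function(d) if (is.null(d)) 0L else nrow(d), 0L))
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    res <- genomic_intervals(character(), integer(), integer())[0, ]
  else
    res <- genomic_intervals(chroms, out$start, out$end)
  attr(res, "n_discarded_positions") <- discarded
  res
}

#' Differentially methylated tiles between two value sets
#'
#' Selects tiles whose methylation difference exceeds `min_diff_pp`
#' percentage points (strictly), partitioned by direction. Both inputs must
#' be [region_methylation()] results over the same tile frame; tiles
#' undefined in either input are excluded. Antisymmetric: swapping the
#' inputs swaps direction labels and preserves membership.
#'
#' @param values_a,values_b [region_methylation()] results on one tile set.
#' @param min_diff_pp minimum absolute difference in percentage points
#'   (default 20; strictly greater than).
#' @return data.frame of selected tiles with `value_a`, `value_b`, `diff`
#'   (b - a) and `direction` (`"b_gt_a"` / `"a_gt_b"`).
#' @export
differential_regions <- function(values_a, values_b, min_diff_pp = 20) {
  key <- function(x) paste(x$chrom, x$start, x$end, sep = "\r")
  if (nrow(values_a) != nrow(values_b) ||
      !identical(sort(key(values_a)), sort(key(values_b))))
    stop("value sets are not over the same tile frame")
  idx <- match(key(values_a), key(values_b))
  a <- values_a$value; b <- values_b$value[idx]
  ok <- !is.na(a) & !is.na(b)
  d <- b - a
  sel <- ok & abs(d) > min_diff_pp
  out <- values_a[sel, c("chrom", "start", "end"), drop = FALSE]
  out$value_a <- a[sel]
  out$value_b <- b[sel]
  out$diff <- d[sel]
  out$direction <- ifelse(d[sel] > 0, "b_gt_a", "a_gt_b")
  rownames(out) <- NULL
  out
}

#' Overlap counts between two tile sets
#'
#' Tiles originate from one common frame, so overlap is tile identity
#' (identical chrom/start/end), not genomic intersection.
#'
#' @param set_a,set_b tile data.frames (chrom, start, end).
#' @return named list: `a_only`, `shared`, `b_only`.
#' @export
overlap_count <- function(set_a, set_b) {
  ka <- unique(paste(set_a$chrom, set_a$start, set_a$end, sep = "\r"))
  kb <- unique(paste(set_b$chrom, set_b$start, set_b$end, sep = "\r"))
  list(a_only = length(setdiff(ka, kb)),
       shared = length(intersect(ka, kb)),
       b_only = length(setdiff(kb, ka)))
}

#' Strand-signed per-position methylation profile
#'
#' Per-position, per-strand percent methylation over a single (consensus)
#' reference, with bottom-strand values negated for strand-parity plotting:
#' asymmetric CH "methylation" between a C-rich and a C-poor strand is the
#' signature of degradation-plus-conversion artefacts rather than biology.
#'
#' @param aln a [bs_alignments()] data.frame.
#' @param reference reference name (must be single).
#' @param contexts context set (default CH = CHG + CHH).
#' @param include_duplicates default TRUE (consensus/repeat references).
#' @return data.frame of class `position_profile`: `pos`, `strand`,
#'   `context`, `meth_count`, `total_count`, `percent`, `signed_percent`.
#' @export
per_position_profile <- function(aln, reference = NULL,
                                 contexts = c("CHG", "CHH"),
                                 include_duplicates = TRUE) {
  if (!is.null(reference)) aln <- aln[aln$chrom %in% reference, , drop = FALSE]
  if (length(unique(aln$chrom)) > 1)
    stop("per-position profiles are defined over a single reference")
  pc <- extract_per_cytosine(aln, contexts = contexts,
                             include_duplicates = include_duplicates)
  pc$signed_percent <- ifelse(pc$strand == "-", -pc$percent, pc$percent)
  class(pc) <- c("position_profile", "data.frame")
  pc
}
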