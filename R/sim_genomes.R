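#' Synthetic random genome with controllable CpG density
#'
#' Draws an i.i.d. base sequence at the requested GC content, then thins
#' CpG dinucleotides towards a target observed/expected ratio by mutating
#' the G of randomly chosen CpGs (a few passes, since mutations can create
#' new CpGs). `cpg_factor = 1` leaves the i.i.d. sequence untouched;
#' `cpg_factor ~ 0.2` with `gc ~ 0.42` gives a mammalian-like context
#' landscape in which CH cytosines outnumber CG cytosines more than
#' twentyfold.
#'
#' @param length sequence length in bases.
#' @param gc GC fraction (default 0.5).
#' @param cpg_factor target CpG observed/expected ratio (default 1).
#' @param name sequence name.
#' @param seed RNG seed.
#' @return a [ref_genome()] with one sequence.
#' @export
synth_genome <- function(length, gc = 0.5, cpg_factor = 1, name = "chr1",
                         seed = NULL) {
  stopifnot(length >= 2, gc > 0, gc < 1, cpg_factor >= 0, cpg_factor <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    b <- sample(names(p), length, replace = TRUE, prob = p)
    if (cpg_factor < 1) {
      repl_p <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
      for (pass in 1:4) {
        cpg_g <- which(b[-length] == "C" & b[-1] == "G") + 1L
        # after earlier passes only the surplus above the target is thinned
        n_exp <- length * p[["C"]] * p[["G"]]
        excess <- length(cpg_g) - cpg_factor * n_exp
        if (excess <= 0) break
        hit <- sample(cpg_g, min(length(cpg_g), round(excess)))
        b[hit] <- sample(names(repl_p), length(hit), replace = TRUE, prob = repl_p)
      }
    }
    ref_genome(setNames(paste(b, collapse = ""), name))
  })
}

#' GC-skewed reference (satellite / mtDNA-like)
#'
#' An i.i.d. sequence whose top strand carries the given C and G fractions,
#' emulating references with asymmetric strand composition (the C-poor top
#' strand at 12-14% C faces a C-rich bottom strand at 23-24% C when
#' `c_top ~ 0.13` and `g_top ~ 0.235`).
#'
#' @param length sequence length.
#' @param c_top,g_top top-strand C and G fractions.
#' @param name sequence name.
#' @param seed RNG seed.
#' @return a [ref_genome()].
#' @export
skewed_reference <- function(length, c_top = 0.13, g_top = 0.235,
                             name = "satellite", seed = NULL) {
  stopifnot(c_top + g_top < 1)
  with_seed(seed, {
    at <- (1 - c_top - g_top) / 2
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c(at, c_top, g_top, at))
    ref_genome(setNames(paste(b, collapse = ""), name))
  })
}

#' Tandem-repeat reference
#'
#' @param motif repeat unit (e.g. `"TTAGGG"`).
#' @param n_units number of units.
#' @param name sequence name.
#' @return a [ref_genome()].
#' @export
tandem_reference <- function(motif, n_units, name = "telomere") {
  ref_genome(setNames(strrep(toupper(motif), n_units), name))
}

#' Synthetic C-poor and C-rich test fragments
#'
#' Two deterministic synthetic DNA fragments with exactly 15% ("C-poor")
#' and 30% ("C-rich") cytosine content on an AT-rich phage-like background,
#' stand-ins for the fragment pair used to titrate bisulfite-induced
#' degradation against cytosine content. They are generated in code (fixed
#' internal shuffle), not taken from any published sequence.
#'
#' @param length fragment length (default 400; must make 0.15*length and
#'   0.30*length whole numbers).
#' @return a [ref_genome()] with sequences `cpoor_synthetic` and
#'   `crich_synthetic`.
#' @export
synthetic_bias_fragments <- function(length = 400L) {
  n_c <- c(cpoor = 0.15, crich = 0.30) * length
  if (any(n_c != round(n_c))) stop("length must make 15% and 30% of it whole numbers")
  build <- function(nc, seed) {
    ng <- round(0.20 * length)
    nat <- length - nc - ng
    pool <- c(rep("C", nc), rep("G", ng),
              rep("A", ceiling(nat / 2)), rep("T", floor(nat / 2)))
    with_seed(seed, paste(sample(pool), collapse = ""))
  }
  ref_genome(c(cpoor_synthetic = build(n_c[["cpoor"]], 151L),
               crich_synthetic = build(n_c[["crich"]], 152L)))
}
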