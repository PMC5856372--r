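# Shared internal helpers.

# Named RNG substreams: one root seed, one derived seed per pipeline stage, so
# that toggling one simulation stage does not perturb the draws of another.
.stage_offsets <- c(
  genome = 11L, methylome = 23L, fragment = 37L, states = 51L,
  conversion = 67L, pcr = 83L, reads = 101L, spike = 127L, misc = 149L
)

stage_seed <- function(seed, stage) {
  off <- .stage_offsets[[stage]]
  if (is.null(off)) stop("unknown RNG stage: ", stage)
  # keep derived seeds well inside 32-bit integer range
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483587)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(.complement[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
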