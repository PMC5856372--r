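#' Bisulfite protocol model
#'
#' Parameters of the generative bisulfite-conversion model.
#'
#' Degradation: bisulfite chemistry causes random base loss at
#' *unmethylated* cytidines followed by backbone breakage, so each
#' unmodified cytosine on a single-strand molecule kills it independently
#' with probability `beta_unmod`; modified cytosines (5mC/5hmC) are
#' protected and break with `beta_mod <= beta_unmod`.
#'
#' Conversion failure: an unmethylated cytosine escapes conversion (a false
#' methylation call) with context-specific marginal probability
#' (`epsilon_CG`, `epsilon_CH`). Failures are molecule-correlated: a
#' fraction `poor_fraction` of molecules are poorly converted and fail at
#' `poor_epsilon` per cytosine, while the remaining molecules fail at the
#' low base rate that keeps the configured epsilon as the marginal rate.
#' This is what makes runs of consecutive unconverted CH calls diagnostic
#' of a bad molecule. Sequence-specific resistance is modelled by
#' `resistant_motifs`, multipliers applied to the failure probability of
#' cytosines inside matching motifs (IUPAC W = A/T supported).
#'
#' Over-conversion: a 5mC is erroneously converted (false negative) with
#' probability `gamma`.
#'
#' @param beta_unmod per-unmodified-cytosine breakage probability.
#' @param beta_mod per-modified-cytosine breakage probability
#'   (must not exceed `beta_unmod`).
#' @param epsilon_CG,epsilon_CH marginal conversion-failure probabilities
#'   by context (unknown-context cytosines use `epsilon_CH`).
#' @param gamma over-conversion probability of modified cytosines.
#' @param poor_fraction fraction of molecules that are poorly converted.
#' @param poor_epsilon per-cytosine failure probability within a poorly
#'   converted molecule (default 0.95).
#' @param resistant_motifs named numeric vector: motif -> failure-probability
#'   multiplier (e.g. `c(CCWGG = 60)`).
#' @return object of class `protocol_model`.
#' @export
protocol_model <- function(beta_unmod = 0, beta_mod = 0,
                           epsilon_CG = 0, epsilon_CH = 0, gamma = 0,
                           poor_fraction = 0, poor_epsilon = 0.95,
                           resistant_motifs = NULL) {
  probs <- c(beta_unmod, beta_mod, epsilon_CG, epsilon_CH, gamma,
             poor_fraction, poor_epsilon)
  if (any(probs < 0 | probs > 1)) stop("all protocol probabilities must lie in [0, 1]")
  if (beta_mod > beta_unmod)
    stop("beta_mod must not exceed beta_unmod (modification protects against degradation)")
  base_eps <- function(eps) {
    if (poor_fraction >= 1) return(0)
    b <- (eps - poor_fraction * poor_epsilon) / (1 - poor_fraction)
    if (b < -1e-12)
      stop("poor_fraction * poor_epsilon exceeds the marginal epsilon ", eps)
    max(b, 0)
  }
  structure(list(beta_unmod = beta_unmod, beta_mod = beta_mod,
                 epsilon_CG = epsilon_CG, epsilon_CH = epsilon_CH,
                 gamma = gamma, poor_fraction = poor_fraction,
                 poor_epsilon = poor_epsilon,
                 base_epsilon_CG = base_eps(epsilon_CG),
                 base_epsilon_CH = base_eps(epsilon_CH),
                 resistant_motifs = resistant_motifs),
            class = "protocol_model")
}

#' PCR amplification model
#'
#' Per cycle, each molecule is copied with success probability
#' `clamp(efficiency_base + efficiency_slope * (g_frac - g_ref), 0, 1)`,
#' where `g_frac` is the molecule's G fraction: a positive slope enriches
#' G-rich molecules, the classic polymerase GC preference. `cycles = 0`
#' reproduces amplification-free behaviour exactly.
#'
#' @param cycles number of PCR cycles (>= 0).
#' @param efficiency_base per-cycle success probability at `g_ref`.
#' @param efficiency_slope dependence of success on molecule G fraction.
#' @param g_ref reference G fraction (default 0.25).
#' @param stochastic binomial per-cycle copying (default TRUE); FALSE uses
#'   the rounded expectation.
#' @return object of class `pcr_model`.
#' @export
pcr_model <- function(cycles = 0L, efficiency_base = 0.8,
                      efficiency_slope = 0, g_ref = 0.25, stochastic = TRUE) {
  if (cycles < 0) stop("cycles must be >= 0")
  if (efficiency_base < 0 || efficiency_base > 1)
    stop("efficiency_base must lie in [0, 1]")
  structure(list(cycles = as.integer(cycles), efficiency_base = efficiency_base,
                 efficiency_slope = efficiency_slope, g_ref = g_ref,
                 stochastic = stochastic),
            class = "pcr_model")
}

#' Methylome model
#'
#' Either context-level probabilities from which per-molecule states are
#' drawn independently, or deterministic/probabilistic per-site
#' probabilities via `site_probs`. `p_hydroxy` is the fraction of modified
#' cytosines carrying 5hmC instead of 5mC (both resist conversion and both
#' protect against degradation in this model).
#'
#' @param p_mCG methylation probability of CpG cytosines.
#' @param p_mCH methylation probability of CHG/CHH cytosines.
#' @param site_probs optional data.frame (chrom, pos, strand, p) overriding
#'   the context-level probability at listed sites.
#' @param p_hydroxy fraction of modified cytosines that are 5hmC.
#' @return object of class `methylome_model`.
#' @export
methylome_model <- function(p_mCG = 0, p_mCH = 0, site_probs = NULL,
                            p_hydroxy = 0) {
  if (any(c(p_mCG, p_mCH, p_hydroxy) < 0 | c(p_mCG, p_mCH, p_hydroxy) > 1))
    stop("methylome probabilities must lie in [0, 1]")
  if (!is.null(site_probs)) {
    need <- c("chrom", "pos", "strand", "p")
    if (!all(need %in% names(site_probs))) stop("site_probs needs columns ",
                                                paste(need, collapse = ", "))
    if (any(site_probs$p < 0 | site_probs$p > 1)) stop("site_probs$p out of [0, 1]")
  }
  structure(list(p_mCG = p_mCG, p_mCH = p_mCH, site_probs = site_probs,
                 p_hydroxy = p_hydroxy),
            class = "methylome_model")
}

#' Block-structured CpG methylome
#'
#' Assigns CpG-site methylation probabilities in consecutive blocks of
#' `block_sites` cytosines, cycling through `levels`. Produces the
#' within-region methylation heterogeneity needed to expose
#' coverage-weighting artefacts of pooled region quantification.
#'
#' @param genome a [ref_genome()].
#' @param levels methylation probabilities cycled block-wise.
#' @param block_sites CpG cytosines per block (default 10).
#' @return a [methylome_model()] with per-site probabilities.
#' @export
blocky_methylome <- function(genome, levels = c(0.1, 0.9), block_sites = 10L) {
  ct <- cytosine_context_table(genome)
  cg <- ct[ct$context == "CG", ]
  blk <- ((seq_len(nrow(cg)) - 1L) %/% block_sites) %% length(levels) + 1L
  methylome_model(site_probs = data.frame(chrom = cg$chrom, pos = cg$pos,
                                          strand = cg$strand, p = levels[blk]))
}

#' Breakage rate calibrated to a fold recovery difference
#'
#' For two equally long unmethylated fragments differing in cytosine
#' fraction by `c_frac_diff`, per-cytosine breakage `beta` yields a
#' post-bisulfite recovery ratio of `(1 - beta)^(-c_frac_diff * length)`.
#' Solving for the observed fold difference:
#' `beta = 1 - fold^(-1 / (c_frac_diff * length))`.
#'
#' @param fold target recovery ratio (C-poor over C-rich).
#' @param c_frac_diff cytosine-fraction difference between the fragments
#'   (default 0.15, i.e. 30% vs 15%).
#' @param length fragment length in bases.
#' @return breakage probability per unmodified cytosine.
#' @export
calibrate_breakage <- function(fold, c_frac_diff = 0.15, length = 400L) {
  if (fold < 1) stop("fold must be >= 1")
  1 - fold^(-1 / (c_frac_diff * length))
}

#' Named protocol presets
#'
#' Illustrative parameter bundles for the main library-preparation
#' families. The absolute rates are not measured constants; they are fitted
#' to the published fold relationships: heat denaturation degrades
#' unmethylated C-rich DNA twice as fast as C-poor (per-fragment 2-fold
#' recovery ratio), alkaline denaturation degrades mildly (1.3-fold) but
#' leaves fourfold more unconverted cytosines, modification protects
#' against breakage, and amplification-free protocols have zero PCR cycles.
#'
#' * `null` - every bias off; the negative control for all diagnostics.
#' * `heat_like` - strong degradation, good conversion, GC-biasing PCR.
#' * `alkaline_like` - mild degradation, 4x the conversion failure, GC-biasing PCR.
#' * `ambs_like` - degradation without cytosine-content dependence modelled
#'   as mild breakage, good conversion, moderate PCR.
#' * `kapa_like` - heat-type degradation and conversion, balanced-G PCR.
#' * `pbat_like` - heat-type degradation and conversion, amplification-free.
#'
#' @param name preset name.
#' @param mean_length mean fragment length the breakage calibration refers
#'   to (default 150).
#' @return list with elements `protocol` and `pcr`.
#' @export
sim_preset <- function(name = c("null", "heat_like", "alkaline_like",
                                "ambs_like", "kapa_like", "pbat_like"),
                       mean_length = 150L) {
  name <- match.arg(name)
  beta_heat <- calibrate_breakage(2, 0.15, mean_length)
  beta_alk <- calibrate_breakage(1.3, 0.15, mean_length)
  # protection: modified C-rich fragments recover ~4x better than
  # unmodified under heat; (1 - beta_mod)^k = 4 * (1 - beta_unmod)^k at
  # k = 0.30 * mean_length
  prot <- function(bu) max(0, 1 - 4^(1 / (0.30 * mean_length)) * (1 - bu))
  eps_heat <- 0.002
  switch(name,
    null = list(protocol = protocol_model(), pcr = pcr_model(cycles = 0L)),
    heat_like = list(
      protocol = protocol_model(beta_unmod = beta_heat, beta_mod = prot(beta_heat),
                                epsilon_CG = eps_heat, epsilon_CH = eps_heat,
                                poor_fraction = eps_heat / 2, poor_epsilon = 0.95),
      pcr = pcr_model(cycles = 12L, efficiency_base = 0.8,
                      efficiency_slope = 0.6)),
    alkaline_like = list(
      protocol = protocol_model(beta_unmod = beta_alk, beta_mod = prot(beta_alk),
                                epsilon_CG = 4 * eps_heat, epsilon_CH = 4 * eps_heat,
                                poor_fraction = 2 * eps_heat, poor_epsilon = 0.95),
      pcr = pcr_model(cycles = 15L, efficiency_base = 0.8,
                      efficiency_slope = 0.6)),
    ambs_like = list(
      protocol = protocol_model(beta_unmod = beta_alk / 2, beta_mod = 0,
                                epsilon_CG = eps_heat, epsilon_CH = eps_heat,
                                poor_fraction = eps_heat / 2, poor_epsilon = 0.95),
      pcr = pcr_model(cycles = 9L, efficiency_base = 0.8,
                      efficiency_slope = 0.4)),
    kapa_like = list(
      protocol = protocol_model(beta_unmod = beta_heat, beta_mod = prot(beta_heat),
                                epsilon_CG = eps_heat, epsilon_CH = eps_heat,
                                poor_fraction = eps_heat / 2, poor_epsilon = 0.95),
      pcr = pcr_model(cycles = 9L, efficiency_base = 0.8,
                      efficiency_slope = -0.1)),
    pbat_like = list(
      protocol = protocol_model(beta_unmod = beta_heat, beta_mod = prot(beta_heat),
                                epsilon_CG = eps_heat, epsilon_CH = eps_heat,
                                poor_fraction = eps_heat / 2, poor_epsilon = 0.95),
      pcr = pcr_model(cycles = 0L)))
}
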