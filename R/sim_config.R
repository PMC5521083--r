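#' Simulation configuration
#'
#' Assembles and validates the parameter set for the synthetic-read generator.
#' Each parameter corresponds to one physical process of a capture-based
#' targeted sequencing protocol; the defaults emulate a ~12-kb panel sequenced
#' to deep unique coverage with 100-bp paired-end reads from mono-nucleosome
#' sized fragments, with per-process error rates of order 1e-5 to 1e-4 per
#' base as observed in quality-filtered deep targeted sequencing data.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param ref_length reference length in bases.
#' @param gc_fraction target G+C fraction of the reference.
#' @param cpg_enrichment multiplier on the CpG dinucleotide frequency relative
#'   to independence (`freq(C) * freq(G)`); human genomic DNA is CpG-depleted
#'   (~0.2-0.3) but 1 keeps the reference neutral by default.
#' @param target_fraction fraction of the reference tiled as capture targets.
#' @param fragment_median,fragment_sd median and standard deviation (bases) of
#'   the rounded log-normal fragment length distribution.
#' @param shear_energy dimensionless acoustic energy scaler (>= 0) multiplying
#'   the oxidative lesion rates; 0 models unsheared (plasma) DNA, 1 the
#'   standard shearing condition, intermediate values milder conditions.
#' @param cleavage_weights named numeric vector of 16 dinucleotide weights
#'   governing where fragment break points fall (the dinucleotide straddles
#'   the broken phosphodiester bond). `NULL` selects the built-in table for
#'   `cleavage_mode`.
#' @param cleavage_mode `"acoustic"` (CG > CA > TA ~ GA preference, with the
#'   bond 5' of A favoured) or `"plasma_nuclease"` (C-before-cut preference).
#' @param p_ox per-G per-strand probability of an oxidative lesion read out as
#'   C:G>A:T, at `shear_energy = 1`, outside NCG:CGN context.
#' @param p_ox2 as `p_ox` for the C:G>G:C-type lesion.
#' @param ncg_multiplier context multiplier applied when the lesioned C:G pair
#'   lies in NCG:CGN context (i.e. in a CpG dinucleotide).
#' @param p_bp probability of an A>K (K = G or T) substitution at a fragment's
#'   first 5' base when that base is A.
#' @param p_hs_CA,p_hs_CT per reference-C probabilities of hybrid-selection
#'   damage on the captured strand, projected as C>A and C>T respectively
#'   (see `hs_strand`).
#' @param hs_strand reference strand carrying hybrid-selection damage:
#'   `"minus"` (default; projected excess C>A/C>T) or `"plus"` (G>T/G>A).
#' @param p_template per-base per-strand probability of a generic template
#'   lesion (library polymerase error / intrinsic damage), uniform over the
#'   three alternative bases; this is the shared plasma/PBL baseline.
#' @param p_seq per-base sequencing-run error probability.
#' @param q_high_given_error probability a sequencing-run error receives a
#'   base quality >= 30.
#' @param q_low_given_correct probability a correctly read base receives a
#'   base quality < 30.
#' @param dup_mean mean PCR duplicate copies per unique molecule (>= 1);
#'   copies are drawn as `1 + Poisson(dup_mean - 1)`.
#' @param snp_density germline SNPs per base.
#' @param n_fragments number of unique molecules per sample.
#' @param read_length read length in bases.
#' @param somatic_spikes `data.frame(pos, alt, af)` of somatic variants to
#'   spike into tumor-like samples (0-based positions), or `NULL`.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, ref_length = 20000, n_fragments = 2000)
#' cfg$fragment_median
#' @export
sim_config <- function(seed = 1L,
                       ref_length = 24000L,
                       gc_fraction = 0.45,
                       cpg_enrichment = 1,
                       target_fraction = 0.5,
                       fragment_median = 170,
                       fragment_sd = 45,
                       shear_energy = 1,
                       cleavage_weights = NULL,
                       cleavage_mode = c("acoustic", "plasma_nuclease"),
                       p_ox = 7e-5,
                       p_ox2 = 1.2e-5,
                       ncg_multiplier = 4,
                       p_bp = 4e-4,
                       p_hs_CA = 1.7e-5,
                       p_hs_CT = 6.5e-6,
                       hs_strand = c("minus", "plus"),
                       p_template = 6e-5,
                       p_seq = 1e-3,
                       q_high_given_error = 0.013,
                       q_low_given_correct = 0.13,
                       dup_mean = 1.5,
                       snp_density = 1e-3,
                       n_fragments = 100000L,
                       read_length = 100L,
                       somatic_spikes = NULL) {
  cleavage_mode <- match.arg(cleavage_mode)
  hs_strand <- match.arg(hs_strand)
  if (is.null(cleavage_weights)) {
    cleavage_weights <- cleavage_weight_table(cleavage_mode)
  }
  cfg <- list(
    seed = as.integer(seed), ref_length = as.integer(ref_length),
    gc_fraction = gc_fraction, cpg_enrichment = cpg_enrichment,
    target_fraction = target_fraction,
    fragment_median = fragment_median, fragment_sd = fragment_sd,
    shear_energy = shear_energy,
    cleavage_weights = cleavage_weights, cleavage_mode = cleavage_mode,
    p_ox = p_ox, p_ox2 = p_ox2, ncg_multiplier = ncg_multiplier,
    p_bp = p_bp, p_hs_CA = p_hs_CA, p_hs_CT = p_hs_CT,
    hs_strand = hs_strand, p_template = p_template,
    p_seq = p_seq, q_high_given_error = q_high_given_error,
    q_low_given_correct = q_low_given_correct,
    dup_mean = dup_mean, snp_density = snp_density,
    n_fragments = as.integer(n_fragments),
    read_length = as.integer(read_length),
    somatic_spikes = somatic_spikes
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Built-in cleavage weight tables
#'
#' Dinucleotide weights for the bond-straddling dinucleotide at fragment break
#' points. The acoustic table encodes the observed cleavage preference
#' CG > CA > TA ~ GA (the bond 5' of A is favoured); the plasma-nuclease table
#' encodes a C-before-cut preference typical of nuclease-generated cfDNA ends.
#'
#' @param mode `"acoustic"` or `"plasma_nuclease"`.
#' @return named numeric vector of 16 weights.
#' @export
cleavage_weight_table <- function(mode = c("acoustic", "plasma_nuclease")) {
  mode <- match.arg(mode)
  dinucs <- DINUCS
  w <- setNames(rep(1, 16), dinucs)
  if (mode == "acoustic") {
    w["CG"] <- 4; w["CA"] <- 3; w["TA"] <- 2; w["GA"] <- 2
  } else {
    w[c("CA", "CC", "CG", "CT")] <- 2
  }
  w
}

validate_sim_config <- function(cfg) {
  probs <- c(
    "gc_fraction", "cpg_enrichment", "target_fraction", "p_ox", "p_ox2",
    "p_bp", "p_hs_CA", "p_hs_CT", "p_template", "p_seq",
    "q_high_given_error", "q_low_given_correct", "snp_density"
  )
  for (nm in setdiff(probs, "cpg_enrichment")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop_bg("invalid config: %s must be a probability in [0,1], got %s", nm, format(v))
    }
  }
  if (cfg$cpg_enrichment < 0) stop_bg("invalid config: cpg_enrichment must be >= 0")
  if (cfg$cpg_enrichment * cfg$gc_fraction / 2 >= 1) {
    stop_bg("invalid config: cpg_enrichment too large for gc_fraction (P(G|C) >= 1)")
  }
  if (cfg$shear_energy < 0) stop_bg("invalid config: shear_energy must be >= 0")
  w <- cfg$cleavage_weights
  if (length(w) != 16L || is.null(names(w)) ||
      !setequal(names(w), DINUCS)) {
    stop_bg("invalid config: cleavage_weights must be a named vector over the 16 dinucleotides")
  }
  if (any(w < 0)) stop_bg("invalid config: cleavage_weights must be non-negative")
  if (all(w == 0)) stop_bg("invalid config: all cleavage weights are zero")
  if (cfg$dup_mean < 1) stop_bg("invalid config: dup_mean must be >= 1")
  if (cfg$fragment_median <= 0 || cfg$fragment_sd < 0) {
    stop_bg("invalid config: fragment length parameters must be positive")
  }
  if (cfg$read_length < 20L) stop_bg("invalid config: read_length must be >= 20")
  if (cfg$n_fragments < 1L) stop_bg("invalid config: n_fragments must be >= 1")
  if (!is.null(cfg$somatic_spikes)) {
    sp <- cfg$somatic_spikes
    if (!is.data.frame(sp) || !all(c("pos", "alt", "af") %in% names(sp))) {
      stop_bg("invalid config: somatic_spikes must be a data.frame with pos, alt, af")
    }
    if (any(sp$af < 0 | sp$af > 1)) stop_bg("invalid config: somatic spike af outside [0,1]")
    if (!all(sp$alt %in% BASES)) stop_bg("invalid config: somatic spike alt not in ACGT")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  reference: %d bp, GC %.2f, CpG enrichment %.2f, %d%% targeted\n",
              x$ref_length, x$gc_fraction, x$cpg_enrichment,
              round(100 * x$target_fraction)))
  cat(sprintf("  fragments: n=%d, median %g bp (sd %g), cleavage '%s'\n",
              x$n_fragments, x$fragment_median, x$fragment_sd, x$cleavage_mode))
  cat(sprintf("  lesions: ox %.2g/%.2g (xNCG %.1f, energy %.2f), bp A>K %.2g, hs %.2g/%.2g (%s), template %.2g\n",
              x$p_ox, x$p_ox2, x$ncg_multiplier, x$shear_energy, x$p_bp,
              x$p_hs_CA, x$p_hs_CT, x$hs_strand, x$p_template))
  cat(sprintf("  sequencing: %d bp reads, p_seq %.2g (Q>=30 given error %.3f), dup mean %.2f\n",
              x$read_length, x$p_seq, x$q_high_given_error, x$dup_mean))
  invisible(x)
}
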