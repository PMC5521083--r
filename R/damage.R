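#' Inject shearing-era damage into a fragment set
#'
#' Places the lesions attributed to the DNA fragmentation step on the
#' double-stranded molecules, strand-resolved, and logs every lesion in a
#' ground-truth ledger:
#'
#' * oxidative guanine lesions (8-oxo-G-like, read out as G>T on the lesioned
#'   strand, i.e. C:G>A:T after pairing; rate `shear_energy * p_ox`, times
#'   `ncg_multiplier` when the C:G pair sits in a CpG dinucleotide, the
#'   NCG:CGN context), and the analogous C:G>G:C lesion at `p_ox2`;
#' * break-point A>K lesions at a fragment's first 5' base when that base is
#'   A, on the strand whose 5' terminus it is, substituting G or T equally.
#'
#' Germline SNPs and somatic spikes, when supplied, are assigned per molecule
#' (duplex substitutions) before damage. `mode = "none"` models plasma DNA:
#' no shearing, so `p_ox`, `p_ox2` and `p_bp` are forced to zero.
#'
#' @param fragments data.table from [draw_fragments()].
#' @param ref a `ref_bundle`.
#' @param config a [sim_config()].
#' @param mode `"acoustic"` (shearing damage active) or `"none"`.
#' @param snps optional data.table (`pos`, `ref`, `alt`, `af`) of germline
#'   SNPs, e.g. from [draw_snps()].
#' @param spikes optional data.frame (`pos`, `alt`, `af`) of somatic variants.
#' @param seed optional seed override.
#' @return object of class `bg_molecules`: list with `molecules` (the
#'   fragment table) and `lesions`, the SimTruth ledger with columns
#'   `mol_id`, `pos` (0-based), `strand` (`+`, `-`, or `*` for duplex),
#'   `ref`, `injected` (base now on the lesioned strand), `proj_alt`
#'   (plus-strand projection) and `process`.
#' @export
apply_damage <- function(fragments, ref, config, mode = c("acoustic", "none"),
                         snps = NULL, spikes = NULL, seed = NULL) {
  mode <- match.arg(mode)
  seed <- seed %||% config$seed
  withr::with_seed(derive_seed(seed, 3L), {
    apply_damage_impl(fragments, ref, config, mode, snps, spikes)
  })
}

apply_damage_impl <- function(fragments, ref, config, mode, snps, spikes) {
  L <- nchar(ref$sequence)
  codes <- base_codes(ref$bytes)
  refch <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  E <- if (mode == "none") 0 else config$shear_energy
  p_bp <- if (mode == "none") 0 else config$p_bp

  # CpG-context flag: position is the C or the G of a CpG dinucleotide
  is_c <- codes == 2L; is_g <- codes == 3L
  cpg <- logical(L)
  cg_start <- which(is_c[-L] & is_g[-1L])
  cpg[cg_start] <- TRUE; cpg[cg_start + 1L] <- TRUE

  out <- list()

  # genotype assignment: duplex substitutions shared by both strands
  assign_af <- function(vars, process) {
    if (is.null(vars) || nrow(vars) == 0L) return(NULL)
    ir_v <- IRanges::IRanges(start = vars$pos + 1L, width = 1L)
    ir_f <- IRanges::IRanges(start = fragments$start + 1L,
                             end = fragments$end)
    ov <- IRanges::findOverlaps(ir_v, ir_f)
    vi <- S4Vectors::queryHits(ov); fi <- S4Vectors::subjectHits(ov)
    carrier <- stats::runif(length(vi)) < vars$af[vi]
    vi <- vi[carrier]; fi <- fi[carrier]
    if (length(vi) == 0L) return(NULL)
    data.table(
      mol_id = fragments$mol_id[fi], pos = vars$pos[vi], strand = "*",
      ref = refch[vars$pos[vi] + 1L], injected = vars$alt[vi],
      proj_alt = vars$alt[vi], process = process
    )
  }
  out$snp <- assign_af(snps, "snp")
  if (!is.null(spikes)) {
    sp <- as.data.table(spikes)
    out$somatic <- assign_af(sp, "somatic")
  }

  # site-class sampler: Bernoulli thinning over all (fragment, eligible site)
  # instances of one position class, exact via sampling-without-replacement
  sample_sites <- function(pos_mask, rate) {
    if (rate <= 0) return(NULL)
    P <- which(pos_mask)                       # 1-based eligible positions
    if (length(P) == 0L) return(NULL)
    cnt <- c(0L, cumsum(pos_mask))             # cnt[i+1] = # eligible in [1, i]
    lo <- cnt[fragments$start + 1L]            # eligible before fragment (0-based start)
    hi <- cnt[fragments$end + 1L]              # eligible through end-1
    ni <- hi - lo
    N <- sum(ni)
    if (N == 0L) return(NULL)
    k <- stats::rbinom(1L, N, rate)
    if (k == 0L) return(NULL)
    u <- sort(sample.int(N, k))
    cum <- cumsum(ni)
    fi <- findInterval(u - 1L, cum) + 1L       # fragment index
    off <- u - c(0L, cum)[fi]                  # 1..ni within fragment
    list(frag = fi, pos = P[lo[fi] + off] - 1L)  # back to 0-based reference pos
  }

  ox_records <- function(pos_mask, rate, lesion_strand, injected_minus, injected_plus, process) {
    s <- sample_sites(pos_mask, rate)
    if (is.null(s)) return(NULL)
    inj <- if (lesion_strand == "+") injected_plus else injected_minus
    data.table(
      mol_id = fragments$mol_id[s$frag], pos = s$pos, strand = lesion_strand,
      ref = refch[s$pos + 1L], injected = inj,
      proj_alt = if (lesion_strand == "+") inj else comp_base(inj),
      process = process
    )
  }

  if (E > 0) {
    m <- config$ncg_multiplier
    # C:G>A:T-type: G -> T on the lesioned strand
    out$ox1 <- rbindlist(list(
      ox_records(is_g & !cpg, E * config$p_ox, "+", NA, "T", "oxidation_CA"),
      ox_records(is_g & cpg, E * config$p_ox * m, "+", NA, "T", "oxidation_CA"),
      ox_records(is_c & !cpg, E * config$p_ox, "-", "T", NA, "oxidation_CA"),
      ox_records(is_c & cpg, E * config$p_ox * m, "-", "T", NA, "oxidation_CA")
    ))
    # C:G>G:C-type: G -> C on the lesioned strand
    out$ox2 <- rbindlist(list(
      ox_records(is_g & !cpg, E * config$p_ox2, "+", NA, "C", "oxidation_CG"),
      ox_records(is_g & cpg, E * config$p_ox2 * m, "+", NA, "C", "oxidation_CG"),
      ox_records(is_c & !cpg, E * config$p_ox2, "-", "C", NA, "oxidation_CG"),
      ox_records(is_c & cpg, E * config$p_ox2 * m, "-", "C", NA, "oxidation_CG")
    ))
  }

  if (p_bp > 0) {
    # plus-strand 5' terminus: first base of the fragment
    a_plus <- which(refch[fragments$start + 1L] == "A")
    hit <- a_plus[stats::runif(length(a_plus)) < p_bp]
    bp_plus <- if (length(hit)) data.table(
      mol_id = fragments$mol_id[hit], pos = fragments$start[hit], strand = "+",
      ref = "A", injected = sample(c("G", "T"), length(hit), replace = TRUE),
      process = "breakpoint_AK"
    ) else NULL
    if (!is.null(bp_plus)) bp_plus[, proj_alt := injected]
    # minus-strand 5' terminus: last fragment base, A on the minus strand
    a_minus <- which(refch[fragments$end] == "T")
    hit2 <- a_minus[stats::runif(length(a_minus)) < p_bp]
    bp_minus <- if (length(hit2)) data.table(
      mol_id = fragments$mol_id[hit2], pos = fragments$end[hit2] - 1L, strand = "-",
      ref = "T", injected = sample(c("G", "T"), length(hit2), replace = TRUE),
      process = "breakpoint_AK"
    ) else NULL
    if (!is.null(bp_minus)) bp_minus[, proj_alt := comp_base(injected)]
    out$bp <- rbindlist(list(bp_plus, bp_minus), use.names = TRUE)
  }

  # generic template lesions: per strand, uniform alternative base
  if (config$p_template > 0) {
    tmpl <- function(strand) {
      s <- sample_sites(rep(TRUE, L), config$p_template)
      if (is.null(s)) return(NULL)
      rb <- refch[s$pos + 1L]
      strand_base <- if (strand == "+") rb else comp_base(rb)
      inj <- random_other_base(strand_base)
      data.table(
        mol_id = fragments$mol_id[s$frag], pos = s$pos, strand = strand,
        ref = rb, injected = inj,
        proj_alt = if (strand == "+") inj else comp_base(inj),
        process = "template"
      )
    }
    out$tmpl <- rbindlist(list(tmpl("+"), tmpl("-")))
  }

  lesions <- rbindlist(out[!vapply(out, is.null, logical(1))], use.names = TRUE)
  if (nrow(lesions) == 0L) {
    lesions <- data.table(
      mol_id = integer(), pos = integer(), strand = character(),
      ref = character(), injected = character(), proj_alt = character(),
      process = character()
    )
  }
  # resolve rare collisions: one surviving record per (molecule, position, strand-visibility class)
  setorder(lesions, mol_id, pos)
  lesions <- unique(lesions, by = c("mol_id", "pos", "strand"))

  structure(list(molecules = copy(fragments), lesions = lesions, mode = mode),
            class = "bg_molecules")
}

# uniformly one of the three bases differing from x (vectorized)
random_other_base <- function(x) {
  idx <- match(x, BASES)
  shift <- sample.int(3L, length(x), replace = TRUE)
  BASES[((idx - 1L + shift) %% 4L) + 1L]
}

#' Draw a germline SNP set
#'
#' @param ref a `ref_bundle`.
#' @param density SNPs per base.
#' @param seed integer seed.
#' @return data.table (`pos` 0-based, `ref`, `alt`, `af`) where `af` is 0.5
#'   (heterozygous, 2/3 of sites) or 1 (homozygous alternative).
#' @export
draw_snps <- function(ref, density, seed) {
  withr::with_seed(derive_seed(seed, 4L), {
    L <- nchar(ref$sequence)
    pos <- which(stats::runif(L) < density) - 1L
    if (length(pos) == 0L) {
      return(data.table(pos = integer(), ref = character(),
                        alt = character(), af = numeric()))
    }
    rb <- substring(ref$sequence, pos + 1L, pos + 1L)
    data.table(
      pos = pos, ref = rb, alt = random_other_base(rb),
      af = sample(c(0.5, 1), length(pos), replace = TRUE, prob = c(2, 1) / 3)
    )
  })
}
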