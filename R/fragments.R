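#' Draw fragments with dinucleotide-weighted break points
#'
#' Samples fragment lengths from a rounded log-normal distribution
#' parameterized by its median and standard deviation (the right-skewed shape
#' of sheared and cell-free DNA libraries), places fragments so that each
#' overlaps at least one capture target, and then refines both break points
#' so that the dinucleotide straddling each broken bond is drawn
#' proportionally to `config$cleavage_weights` among the locally available
#' bonds. The 5' start bond is weighted by the plus-strand dinucleotide; the
#' end bond by the reverse complement (the same chemistry seen from the minus
#' strand, whose 5' end it is).
#'
#' @param ref a `ref_bundle`.
#' @param config a [sim_config()]; uses `fragment_median`, `fragment_sd`,
#'   `cleavage_weights`.
#' @param n number of fragments (defaults to `config$n_fragments`).
#' @param seed optional seed override.
#' @return data.table with `mol_id`, `start`, `end` (0-based half-open).
#' @export
draw_fragments <- function(ref, config, n = config$n_fragments, seed = NULL) {
  if (n < 1L) stop_bg("n must be >= 1")
  if (all(config$cleavage_weights == 0)) stop_bg("invalid config: all cleavage weights are zero")
  seed <- seed %||% config$seed
  withr::with_seed(derive_seed(seed, 2L), {
    draw_fragments_impl(ref, config, n)
  })
}

draw_fragments_impl <- function(ref, config, n) {
  L <- nchar(ref$sequence)
  m <- config$fragment_median
  v <- config$fragment_sd^2
  # log-normal with median m and linear-scale variance v:
  # exp(s^2) solves x^2 - x = v/m^2
  x <- (1 + sqrt(1 + 4 * v / m^2)) / 2
  sdlog <- sqrt(log(x))

  tmask <- target_mask(ref)
  tcum <- c(0L, cumsum(tmask))
  wpad <- 12L  # local bond-refinement window half-width + margin

  starts <- integer(0); lens <- integer(0)
  while (length(starts) < n) {
    k <- max(2L * (n - length(starts)), 1000L)
    len <- pmax(20L, as.integer(round(stats::rlnorm(k, log(m), sdlog))))
    len <- pmin(len, L - 2L * wpad - 2L)
    s <- wpad + as.integer(floor(stats::runif(k) * (L - len - 2L * wpad)))
    # keep fragments overlapping >= 1 target base (capture enrichment)
    keep <- (tcum[s + len + 1L] - tcum[s + 1L]) > 0L
    starts <- c(starts, s[keep]); lens <- c(lens, len[keep])
  }
  starts <- starts[seq_len(n)]; lens <- lens[seq_len(n)]
  ends <- starts + lens

  w <- config$cleavage_weights[DINUCS]
  codes <- base_codes(ref$bytes)
  # bond at position b sits between b-1 and b; dinucleotide code for bond b
  bond_dinuc <- function(b) (codes[b] - 1L) * 4L + codes[b + 1L]  # b is 0-based bond pos
  logw <- log(as.numeric(w))
  rc_index <- revcomp_dinuc_index()

  refine <- function(b, use_rc) {
    offs <- -10:10
    cand <- outer(b, offs, `+`)                       # n x 21 bond positions
    dc <- matrix(bond_dinuc(as.vector(cand)), nrow = length(b))
    if (use_rc) dc <- matrix(rc_index[as.vector(dc)], nrow = length(b))
    g <- -log(-log(matrix(stats::runif(length(dc)), nrow = nrow(dc))))
    pick <- max.col(matrix(logw[as.vector(dc)], nrow = nrow(dc)) + g, ties.method = "first")
    cand[cbind(seq_along(b), pick)]
  }
  new_start <- refine(starts, use_rc = FALSE)
  new_end <- refine(ends, use_rc = TRUE)
  bad <- (new_end - new_start) < 20L
  new_start[bad] <- starts[bad]; new_end[bad] <- ends[bad]

  data.table(mol_id = seq_len(n), start = new_start, end = new_end)
}

# 1..16 dinucleotide code of the reverse complement dinucleotide
revcomp_dinuc_index <- function() {
  dinucs <- DINUCS
  rc <- revcomp(dinucs)
  match(rc, dinucs)
}

base_codes <- function(bytes) {
  lut <- integer(256)
  lut[as.integer(BASE_BYTES) + 1L] <- 1:4
  lut[as.integer(bytes) + 1L]
}
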