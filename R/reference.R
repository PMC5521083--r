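#' Generate a synthetic reference and capture targets
#'
#' Builds a random reference sequence with a prescribed G+C fraction and CpG
#' dinucleotide enrichment, and tiles a fraction of it as capture target
#' intervals. The sequence is a first-order Markov chain whose C-row boosts
#' (or depletes) the C->G transition so that the CpG frequency is
#' approximately `cpg_enrichment * freq(C) * freq(G)`, with the remaining
#' transition rows compensated so the marginal base composition still matches
#' `gc_fraction`.
#'
#' @param config a [sim_config()] object.
#' @param seed optional seed override (defaults to `config$seed`).
#' @return an object of class `ref_bundle`: a list with `name`, `sequence`
#'   (character string over ACGT), `targets` (data.table of 0-based half-open
#'   intervals, sorted and non-overlapping) and cached byte representation.
#' @examples
#' ref <- make_reference(sim_config(seed = 1, ref_length = 5000))
#' substr(ref$sequence, 1, 40)
#' @export
make_reference <- function(config, seed = NULL) {
  if (config$ref_length < 10L * config$read_length) {
    stop_bg("invalid config: ref_length (%d) must be >= 10 * read_length (%d)",
            config$ref_length, 10L * config$read_length)
  }
  seed <- seed %||% config$seed
  L <- config$ref_length
  gc <- config$gc_fraction
  e <- config$cpg_enrichment
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  codes <- withr::with_seed(derive_seed(seed, 1L), {
    markov_codes(L, p, e)
  })
  seq <- rawToChar(BASE_BYTES[codes])
  targets <- tile_targets(L, config$target_fraction)
  structure(
    list(name = "chrS", sequence = seq, bytes = charToRaw(seq), targets = targets),
    class = "ref_bundle"
  )
}

# first-order Markov chain over base codes 1..4 with a CpG-adjusted C row
markov_codes <- function(L, p, e) {
  pG <- p[["G"]]; pC <- p[["C"]]
  if (pG == 0) {
    return(sample.int(4L, L, replace = TRUE, prob = p))
  }
  # C row: exact P(G|C) = e * pG, remainder spread over A/C/T proportionally
  qGC <- min(e * pG, 0.999)
  restC <- p[c("A", "C", "T")]
  restC <- if (sum(restC) > 0) (1 - qGC) * restC / sum(restC) else c(A = 0, C = 1 - qGC, T = 0)
  rowC <- c(restC[["A"]], restC[["C"]], qGC, restC[["T"]])
  # other rows: compensate so marginal G frequency stays pG
  qGO <- max(0, min(1, pG * (1 - pC * e) / (1 - pC)))
  restO <- p[c("A", "C", "T")]
  restO <- if (sum(restO) > 0) (1 - qGO) * restO / sum(restO) else c(A = 0, C = 1 - qGO, T = 0)
  rowO <- c(restO[["A"]], restO[["C"]], qGO, restO[["T"]])

  u <- stats::runif(L)
  nxtC <- findInterval(u, cumsum(rowC)[1:3]) + 1L
  nxtO <- findInterval(u, cumsum(rowO)[1:3]) + 1L
  x <- integer(L)
  x[1L] <- sample.int(4L, 1L, prob = p)
  for (i in 2:L) {
    x[i] <- if (x[i - 1L] == 2L) nxtC[i] else nxtO[i]
  }
  x
}

# tile target blocks across the reference, keeping a margin clear of the
# edges so break-point windows and flanking contexts never run off the end
tile_targets <- function(L, fraction, block = 500L, margin = 60L) {
  usable <- L - 2L * margin
  if (fraction >= 0.999) {
    return(data.table(start = margin, end = L - margin))
  }
  period <- max(block + 50L, as.integer(round(block / max(fraction, 1e-6))))
  starts <- seq.int(margin, L - margin - block, by = period)
  if (length(starts) == 0L) starts <- margin
  data.table(start = as.integer(starts), end = as.integer(starts + block))
}

#' @export
print.ref_bundle <- function(x, ...) {
  nt <- nchar(x$sequence)
  tb <- sum(x$targets$end - x$targets$start)
  cat(sprintf("<ref_bundle> %s: %d bp, %d target intervals covering %d bp (%.1f%%)\n",
              x$name, nt, nrow(x$targets), tb, 100 * tb / nt))
  invisible(x)
}

# logical mask of target membership over reference positions (0-based index i
# maps to element i+1)
target_mask <- function(ref) {
  L <- nchar(ref$sequence)
  m <- logical(L)
  for (i in seq_len(nrow(ref$targets))) {
    m[(ref$targets$start[i] + 1L):ref$targets$end[i]] <- TRUE
  }
  m
}

#' Write and read reference/target files
#'
#' `write_reference()` writes the reference as FASTA and the targets as a
#' 0-based half-open BED file; `read_reference()` reads them back into a
#' `ref_bundle`.
#'
#' @param ref a `ref_bundle`.
#' @param fasta,bed file paths.
#' @return `read_reference()` returns a `ref_bundle`.
#' @export
write_reference <- function(ref, fasta, bed) {
  ss <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(ss, fasta)
  gr <- GenomicRanges::GRanges(
    ref$name,
    IRanges::IRanges(start = ref$targets$start + 1L, end = ref$targets$end)
  )
  rtracklayer::export(gr, bed, format = "BED")
  invisible(c(fasta = fasta, bed = bed))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, bed) {
  ss <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(bed, format = "BED")
  seq <- as.character(ss[[1L]])
  targets <- data.table(
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  setorder(targets, start)
  structure(
    list(name = names(ss)[1L], sequence = seq, bytes = charToRaw(seq), targets = targets),
    class = "ref_bundle"
  )
}
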