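# Internal helpers shared across modules. DNA is handled as raw bytes
# (charToRaw) in hot paths; Biostrings is used at the file-format boundary.

BASES <- c("A", "C", "G", "T")
BASE_BYTES <- charToRaw("ACGT")

# the 16 dinucleotides in first-base-major order, so that the code of
# (c1, c2) is (c1 - 1) * 4 + c2 with base codes 1..4
DINUCS <- paste0(rep(BASES, each = 4L), rep(BASES, 4L))

#' @importFrom data.table data.table setDT setkey setorder := .N .SD fifelse rbindlist
NULL

# complement lookup over raw bytes (A<->T, C<->G); other bytes pass through
comp_byte_table <- local({
  tab <- as.raw(0:255)
  tab[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  tab
})

comp_bytes <- function(x) comp_byte_table[as.integer(x) + 1L]

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(x, function(s) rawToChar(rev(comp_bytes(charToRaw(s)))), character(1))
}

# The 12 strand-resolved substitution classes, ordered by source base
SUB_CLASSES <- c(
  "A>C", "A>G", "A>T",
  "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T",
  "T>A", "T>C", "T>G"
)

# The 6 strand-collapsed classes (pyrimidine-first convention)
COLLAPSED_CLASSES <- c(
  "C:G>A:T", "C:G>G:C", "C:G>T:A",
  "T:A>A:T", "T:A>C:G", "T:A>G:C"
)

# strand-resolved -> collapsed mapping
collapse_map <- function() {
  c(
    "C>A" = "C:G>A:T", "G>T" = "C:G>A:T",
    "C>G" = "C:G>G:C", "G>C" = "C:G>G:C",
    "C>T" = "C:G>T:A", "G>A" = "C:G>T:A",
    "T>A" = "T:A>A:T", "A>T" = "T:A>A:T",
    "T>C" = "T:A>C:G", "A>G" = "T:A>C:G",
    "T>G" = "T:A>G:C", "A>C" = "T:A>G:C"
  )
}

sub_class <- function(ref, alt) paste0(ref, ">", alt)

# the three alternative bases for each reference base
ALT_LOOKUP <- list(
  A = c("C", "G", "T"), C = c("A", "G", "T"),
  G = c("A", "C", "T"), T = c("A", "C", "G")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds below 2^31, derived from a parent seed.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 11 * as.numeric(k)) %% 2147483629 + 1
}

# reference width of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    len <- as.integer(sub("[A-Z=]$", "", m))
    op <- sub("^\\d+", "", m)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

has_clipping <- function(cigar) grepl("[SH]", cigar)

stop_bg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
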