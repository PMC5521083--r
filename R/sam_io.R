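#' Write alignment records to SAM
#'
#' Emits a coordinate-sorted SAM file with `@HD`/`@SQ` headers from a read
#' table (as produced by [generate_reads()] or [read_alignments()]).
#' Positions are converted from the package's 0-based half-open convention to
#' SAM's 1-based coordinates.
#'
#' @param reads read data.table.
#' @param path output path (`.sam`).
#' @param ref_length reference length for the `@SQ` header.
#' @param ref_name reference name.
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, path, ref_length, ref_name = reads$rname[1]) {
  r <- as.data.table(reads)
  setorder(r, pos, qname, mate)
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_length))
  )
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    r$qname, r$flag, r$rname, r$pos + 1L, 60L, r$cigar,
    "=", r$mpos + 1L, r$tlen, r$seq, r$qual
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted with `Rsamtools::asBam()` and both are scanned with
#' `Rsamtools::scanBam()`. Only ungapped records (CIGAR of M, optionally with
#' clipping, no indels) are representable; records with indels raise an
#' error since no downstream estimator is defined for them.
#'
#' @param path `.sam` or `.bam` file.
#' @return read data.table in the package's internal layout (0-based `pos`).
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand",
             "seq", "qual", "mpos", "isize")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (any(grepl("[ID]", b$cigar))) stop_bg("indel-containing CIGARs are not supported")
  dt <- data.table(
    qname = b$qname,
    flag = as.integer(b$flag),
    rname = as.character(b$rname),
    pos = as.integer(b$pos) - 1L,
    len = cigar_ref_width(b$cigar),
    strand = fifelse(bitwAnd(as.integer(b$flag), 16L) > 0L, "-", "+"),
    mate = fifelse(bitwAnd(as.integer(b$flag), 64L) > 0L, 1L, 2L),
    cigar = b$cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    mpos = as.integer(b$mpos) - 1L,
    tlen = as.integer(b$isize)
  )
  setorder(dt, pos, qname, mate)
  dt[]
}

#' Write a simulated sample to disk
#'
#' Writes the SAM file and the ground-truth ledger TSVs for one simulated
#' sample.
#'
#' @param sample a `bg_sample` from [generate_reads()].
#' @param dir output directory.
#' @param ref a `ref_bundle`.
#' @return named character vector of written paths.
#' @export
write_sample <- function(sample, dir, ref) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, sample$sample_name)
  sam <- paste0(base, ".sam")
  write_sam(sample$reads, sam, ref_length = nchar(ref$sequence), ref_name = ref$name)
  truth <- paste0(base, "_truth.tsv")
  les <- copy(sample$lesions)
  utils::write.table(les, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  mols <- paste0(base, "_molecules.tsv")
  utils::write.table(sample$molecules, mols, sep = "\t", quote = FALSE, row.names = FALSE)
  serr <- paste0(base, "_seqerrors.tsv")
  utils::write.table(sample$seq_errors, serr, sep = "\t", quote = FALSE, row.names = FALSE)
  c(sam = sam, truth = truth, molecules = mols, seq_errors = serr)
}
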