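#' Mate overlap intervals
#'
#' For each proper pair, the half-open reference interval covered by both
#' mates (possibly empty). Pairs with mates on different contigs are skipped
#' and counted in the `"skipped"` attribute.
#'
#' @param records read data.table (both mates present per `qname`).
#' @return data.table `qname`, `start`, `end` (0-based half-open;
#'   `end <= start` means no overlap).
#' @export
find_overlaps <- function(records) {
  r <- as.data.table(records)
  rn <- r[, .(n_contig = length(unique(rname)),
              s1 = pos[mate == 1L][1], e1 = (pos + len)[mate == 1L][1],
              s2 = pos[mate == 2L][1], e2 = (pos + len)[mate == 2L][1]),
          by = qname]
  skipped <- sum(rn$n_contig > 1L)
  rn <- rn[n_contig == 1L]
  out <- rn[, .(qname, start = pmax(s1, s2), end = pmin(e1, e2))]
  setattr(out, "skipped", skipped)
  out[]
}

#' Read 1 / read 2 consistency of background errors in mate overlaps
#'
#' Within mate-overlap regions, scores every site where at least one mate
#' shows a background-category non-reference allele at quality >= `qmin`
#' and the partner base also has quality >= `qmin` (a high-quality alt
#' facing a quality-censored partner base is excluded rather than counted
#' discordant). A site is `consistent` when both mates show the same alt
#' allele -- the signature of an error present in the template before the
#' sequencing run -- and `inconsistent` otherwise, the signature of an
#' error incurred during the run itself.
#'
#' @param records filtered read data.table.
#' @param table a `bg_background` table defining background-category alleles.
#' @param ref a `ref_bundle`.
#' @param qmin base quality gate applied to both mates.
#' @return list of class `bg_overlap_stats`: `n_overlap_bases`,
#'   `n_error_sites`, `n_consistent`, `n_inconsistent`,
#'   `fraction_inconsistent` (NA when no sites scored).
#' @export
consistency_fractions <- function(records, table, ref, qmin = 30L) {
  r <- as.data.table(records)
  stopifnot(inherits(table, "bg_background"))
  ov <- find_overlaps(r)
  ov <- ov[end > start]
  out <- list(n_overlap_bases = 0, n_error_sites = 0L,
              n_consistent = 0L, n_inconsistent = 0L,
              fraction_inconsistent = NA_real_)
  class(out) <- "bg_overlap_stats"
  if (nrow(ov) == 0L) return(out)
  out$n_overlap_bases <- sum(ov$end - ov$start)

  # expand only overlap segments of each mate
  r <- merge(r, ov, by = "qname", suffixes = c("", ".ov"))
  r <- r[end > start]
  off <- r$start - r$pos                       # offset of overlap within read
  olen <- r$end - r$start
  idx <- sequence(olen, from = r$start + 1L)   # 1-based ref positions
  rrow <- rep.int(seq_len(nrow(r)), olen)
  # base/qual bytes at overlap offsets
  sub_seq <- substring(r$seq, off + 1L, off + olen)
  sub_qual <- substring(r$qual, off + 1L, off + olen)
  bcode <- base_codes(charToRaw(paste(sub_seq, collapse = "")))
  qv <- as.integer(charToRaw(paste(sub_qual, collapse = ""))) - 33L

  dt <- data.table(qname = r$qname[rrow], mate = r$mate[rrow],
                   pos = idx - 1L, base = BASES[bcode], qual = qv)
  wide <- merge(dt[mate == 1L, .(qname, pos, b1 = base, q1 = qual)],
                dt[mate == 2L, .(qname, pos, b2 = base, q2 = qual)],
                by = c("qname", "pos"))
  wide <- wide[q1 >= qmin & q2 >= qmin]
  if (nrow(wide) == 0L) return(out)
  refch <- rawToChar(ref$bytes, multiple = TRUE)
  wide[, ref := refch[pos + 1L]]

  bgset <- table[category == "background", .(pos, alt)]
  cand <- wide[b1 != ref | b2 != ref]
  hit1 <- merge(cand[b1 != ref], bgset, by.x = c("pos", "b1"), by.y = c("pos", "alt"))
  hit2 <- merge(cand[b2 != ref], bgset, by.x = c("pos", "b2"), by.y = c("pos", "alt"))
  scored <- unique(rbindlist(list(
    hit1[, .(qname, pos, b1, b2)],
    hit2[, .(qname, pos, b1, b2)]
  ), use.names = TRUE))
  if (nrow(scored) == 0L) return(out)
  out$n_error_sites <- nrow(scored)
  out$n_consistent <- sum(scored$b1 == scored$b2)
  out$n_inconsistent <- out$n_error_sites - out$n_consistent
  out$fraction_inconsistent <- out$n_inconsistent / out$n_error_sites
  out
}

#' @export
print.bg_overlap_stats <- function(x, ...) {
  cat(sprintf("<bg_overlap_stats> %d overlap bases, %d scored error sites: %d consistent, %d inconsistent (%.1f%%)\n",
              x$n_overlap_bases, x$n_error_sites, x$n_consistent,
              x$n_inconsistent, 100 * (x$fraction_inconsistent %||% NA)))
  invisible(x)
}
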